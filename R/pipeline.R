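#' Default end-to-end run configuration
#'
#' The worked-example pipeline at desk scale: a 200 x 150 px frame (0.05
#' mm/px), three lights, a reduced 480-620 nm filter sweep, one 3 x 1.5 mm
#' flavin-like stain, detection in the green/500 nm channel at threshold
#' 0.35, k-means with k = 2 over a crop around the stain, and 10 px tiles.
#'
#' @param seed Top-level seed; stage seeds fan out by fixed offsets.
#' @param noise_sd Sensor noise sd.
#' @return Nested configuration list for [run_all()].
#' @export
default_run_config <- function(seed = 0L, noise_sd = 0.02) {
  list(
    seed = as.integer(seed),
    protocol = list(filter_min = 480, filter_max = 620, increment = 20,
                    frame_width = 200, frame_height = 150),
    scene = list(noise_sd = noise_sd, concentration = 1),
    detect = list(light = "green", filter_nm = 500, threshold = 0.35,
                  region = c(x0 = 50, y0 = 45, width = 100, height = 60)),
    cluster = list(k = 2, n_restarts = 10),
    tiles = list(tile_size = 10, coverage = 0.5, min_dirty = 1,
                 lambda = 1e-3)
  )
}

#' Run the full pipeline: simulate, detect, cluster, tile-classify, report
#'
#' Generates one dirty/clean phantom pair, runs the threshold-differencing
#' detector and the full-cube k-means segmenter over the configured region,
#' trains the tile classifier on truth-labeled tiles of the pair and calls
#' both surfaces, and (optionally) benchmarks a hygiene sample CSV. All
#' artifacts (PNG stacks, masks, overlay, JSON report) are written under
#' `out_dir` and are byte-identical across reruns with the same config and
#' seed.
#'
#' @param config Configuration list, see [default_run_config()]; may also
#'   carry `hygiene_csv` (path of a per-sample CSV) and `scene_yaml` (path of
#'   a scene/protocol YAML overriding the inline protocol/scene blocks).
#' @param out_dir Output directory.
#' @return The run report (also written as `report.json`), invisibly.
#' @export
run_all <- function(config = default_run_config(), out_dir = tempfile("run")) {
  seed <- config$seed %||% 0L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$scene_yaml)) {
    sc <- read_scene_config(config$scene_yaml)
    protocol <- sc$protocol
    scene <- sc$scene
    scene$seed <- as.integer(seed)
  } else {
    p <- config$protocol
    protocol <- make_protocol(default_lights(),
                              filter_min = p$filter_min,
                              filter_max = p$filter_max,
                              increment = p$increment,
                              frame_width = p$frame_width,
                              frame_height = p$frame_height)
    scene <- default_scene(protocol,
                           noise_sd = config$scene$noise_sd %||% 0.02,
                           seed = seed,
                           concentration = config$scene$concentration %||% 1)
    if (isTRUE(config$scene$empty)) scene$stains <- list()
  }

  message("stage simulate: seed ", seed, ", ",
          nrow(protocol$channels), " channels, ",
          protocol$frame_width, " x ", protocol$frame_height, " px")
  pair <- render_pair(scene, protocol)
  write_stack(pair$dirty, file.path(out_dir, "dirty"))
  write_stack(pair$clean, file.path(out_dir, "clean"))
  write_mask(pair$truth, file.path(out_dir, "truth.png"))

  d <- config$detect
  region <- px_region(d$region[["x0"]], d$region[["y0"]],
                      d$region[["width"]], d$region[["height"]])
  rows <- region$y0 + seq_len(region$height)
  cols <- region$x0 + seq_len(region$width)
  truth_crop <- stain_mask(pair$truth$mask[rows, cols], "planted (crop)")

  message("stage detect: ", d$light, "/", d$filter_nm, " nm, threshold ",
          d$threshold)
  dirty_fr <- select_channel(crop(pair$dirty, region), d$light, d$filter_nm)
  clean_fr <- select_channel(crop(pair$clean, region), d$light, d$filter_nm)
  diff_mask <- differential_mask(dirty_fr, clean_fr, d$threshold)
  write_mask(diff_mask, file.path(out_dir, "differential_mask.png"))
  j_diff <- jaccard(diff_mask, truth_crop)

  message("stage cluster: k = ", config$cluster$k)
  # a constant region (e.g. a noise-free empty scene) has nothing to
  # segment: report an empty stain instead of a degenerate-input error
  km <- tryCatch(
    kmeans_cluster(pair$dirty, region,
                   k = config$cluster$k %||% 2,
                   seed = seed + 1L,
                   background_channel = list(d$light, d$filter_nm),
                   n_restarts = config$cluster$n_restarts %||% 10),
    error = function(e) {
      if (!grepl("degenerate input", conditionMessage(e))) stop(e)
      list(mask = stain_mask(matrix(FALSE, region$height, region$width),
                             "k-means (degenerate region, empty)"),
           k = config$cluster$k %||% 2)
    }
  )
  write_mask(km$mask, file.path(out_dir, "kmeans_mask.png"))
  png::writePNG(overlay_render(km, dirty_fr$frame),
                file.path(out_dir, "kmeans_overlay.png"))
  j_km <- jaccard(km$mask, truth_crop)

  message("stage tiles: ", config$tiles$tile_size, " px tiles")
  grid <- make_grid(region, config$tiles$tile_size %||% 10)
  feat_dirty <- tile_features(pair$dirty, grid)
  feat_clean <- tile_features(pair$clean, grid)
  lab_dirty <- label_tiles(grid, pair$truth,
                           coverage = config$tiles$coverage %||% 0.5)
  if (length(unique(lab_dirty)) < 2) {
    # no dirty training tiles (null scene): nothing to learn, call clean
    n_t <- length(grid$tiles)
    call_dirty <- list(surface_call = "clean", dirty_fraction = 0,
                       n_tiles = n_t)
    call_clean <- call_dirty
  } else {
    model <- svm_train(rbind(feat_dirty, feat_clean),
                       c(lab_dirty, rep("clean", nrow(feat_clean))),
                       lambda = config$tiles$lambda %||% 1e-3,
                       seed = seed + 2L)
    call_dirty <- classify_surface(model, feat_dirty,
                                   config$tiles$min_dirty %||% 1)
    call_clean <- classify_surface(model, feat_clean,
                                   config$tiles$min_dirty %||% 1)
  }

  report <- list(
    seed = seed,
    n_channels = nrow(protocol$channels),
    frame = c(width = protocol$frame_width, height = protocol$frame_height),
    detection = list(
      channel = paste0(d$light, "/", d$filter_nm),
      threshold = d$threshold,
      jaccard_differential = j_diff,
      differential_area_mm2 = mask_summary(diff_mask,
                                           scene$pixel_scale)$area_mm2
    ),
    kmeans = list(k = km$k, jaccard = j_km,
                  stain_area_mm2 = mask_summary(km$mask,
                                                scene$pixel_scale)$area_mm2),
    tiles = list(n_tiles = call_dirty$n_tiles,
                 dirty_surface_call = call_dirty$surface_call,
                 dirty_fraction = call_dirty$dirty_fraction,
                 clean_surface_call = call_clean$surface_call,
                 clean_dirty_fraction = call_clean$dirty_fraction),
    artifacts = list(dirty = "dirty/manifest.tsv",
                     clean = "clean/manifest.tsv",
                     truth = "truth.png",
                     differential_mask = "differential_mask.png",
                     kmeans_mask = "kmeans_mask.png",
                     kmeans_overlay = "kmeans_overlay.png",
                     report = "report.json")
  )

  if (!is.null(config$hygiene_csv)) {
    message("stage hygiene: ", config$hygiene_csv)
    samples <- read_hygiene_samples(config$hygiene_csv)
    verdicts <- hygiene_verdicts(samples)
    utils::write.csv(verdicts, file.path(out_dir, "hygiene_verdicts.csv"),
                     row.names = FALSE)
    report$hygiene <- list(
      n_samples = nrow(verdicts),
      atp_dirty = sum(verdicts$atp_status == "dirty"),
      tpc_exceeds = sum(verdicts$tpc_status %in%
                          c("exceeds_benchmark", "heavy_growth")),
      heavy_growth = sum(verdicts$tpc_status == "heavy_growth")
    )
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
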