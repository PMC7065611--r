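#' Stain region of a synthetic scene
#'
#' A rectangular or elliptical patch of fluorescent soil, positioned in scene
#' (mm) coordinates: x rightward, y downward, origin at the top-left corner.
#'
#' @param shape `"rectangle"` or `"ellipse"`.
#' @param center Length-2 numeric, (x, y) of the region center in mm.
#' @param extent Length-2 numeric, full (width, height) in mm; both positive.
#' @param fluor A [fluorophore()].
#' @param concentration Non-negative dimensionless surface density.
#' @return An object of class `stain_region`.
#' @export
stain_region <- function(shape = c("rectangle", "ellipse"),
                         center, extent,
                         fluor = fluorophore(), concentration = 1) {
  shape <- match.arg(shape)
  if (length(center) != 2 || length(extent) != 2 || any(extent <= 0)) {
    stop("center and extent must be length-2; extent strictly positive",
         call. = FALSE)
  }
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  structure(
    list(shape = shape, center = as.numeric(center),
         extent = as.numeric(extent), fluor = fluor,
         concentration = concentration),
    class = "stain_region"
  )
}

#' Synthetic scene specification
#'
#' A declarative description of one surface: flat background reflectance, a
#' list of planted stains, i.i.d. Gaussian sensor noise, and the pixel scale
#' relating scene millimetres to sensor pixels. The clean variant of the same
#' scene is identical except that the stain list is empty. The default pixel
#' scale, 0.05 mm/px, puts the worked-example 3 x 1.5 mm invisible stain at
#' 60 x 30 px.
#'
#' @param pixel_scale mm per px.
#' @param background_reflectance Baseline intensity, either one value for all
#'   channels or one per channel, in \[0, 1\].
#' @param stains List of [stain_region()] objects.
#' @param noise_sd Gaussian noise sd on the \[0, 1\] intensity scale.
#' @param seed Integer RNG seed; identical seeds reproduce identical stacks.
#' @param leakage_gain Amplitude of the excitation-light leak-through term;
#'   at full drive with light on filter this alone can saturate the sensor.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(pixel_scale = 0.05,
                       background_reflectance = 0.2,
                       stains = list(),
                       noise_sd = 0.02,
                       seed = 0L,
                       leakage_gain = 1.2) {
  if (pixel_scale <= 0) stop("pixel_scale must be positive", call. = FALSE)
  if (any(background_reflectance < 0) || any(background_reflectance > 1)) {
    stop("background_reflectance must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!all(vapply(stains, inherits, logical(1), "stain_region"))) {
    stop("stains must be a list of stain_region objects", call. = FALSE)
  }
  structure(
    list(pixel_scale = pixel_scale,
         background_reflectance = background_reflectance,
         stains = stains, noise_sd = noise_sd,
         seed = as.integer(seed), leakage_gain = leakage_gain),
    class = "scene_spec"
  )
}

#' The default worked-example phantom scene
#'
#' One 3 x 1.5 mm rectangular flavin-like stain centered in the frame on a
#' 0.2-reflectance background, the configuration every detection example in
#' the package exercises.
#'
#' @param protocol Protocol whose frame size places the stain.
#' @param noise_sd,seed Passed to [scene_spec()].
#' @param concentration Stain surface density.
#' @return A `scene_spec`.
#' @export
default_scene <- function(protocol, noise_sd = 0.02, seed = 0L,
                          concentration = 1) {
  cx <- protocol$frame_width / 2 * 0.05
  cy <- protocol$frame_height / 2 * 0.05
  scene_spec(
    stains = list(stain_region("rectangle", center = c(cx, cy),
                               extent = c(3, 1.5),
                               concentration = concentration)),
    noise_sd = noise_sd, seed = seed
  )
}

# Pixel-center membership mask of one stain region. Pixel (row r, col c),
# 0-based, has center ((c + 0.5) * scale, (r + 0.5) * scale) mm.
region_pixel_mask <- function(region, height, width, pixel_scale) {
  x <- (seq_len(width) - 0.5) * pixel_scale
  y <- (seq_len(height) - 0.5) * pixel_scale
  dx <- abs(outer(rep(1, height), x) - region$center[1])
  dy <- abs(outer(y, rep(1, width)) - region$center[2])
  if (region$shape == "rectangle") {
    dx < region$extent[1] / 2 & dy < region$extent[2] / 2
  } else {
    (dx / (region$extent[1] / 2))^2 + (dy / (region$extent[2] / 2))^2 < 1
  }
}

check_scene_bounds <- function(scene, protocol) {
  w_mm <- protocol$frame_width * scene$pixel_scale
  h_mm <- protocol$frame_height * scene$pixel_scale
  for (s in scene$stains) {
    x0 <- s$center[1] - s$extent[1] / 2
    x1 <- s$center[1] + s$extent[1] / 2
    y0 <- s$center[2] - s$extent[2] / 2
    y1 <- s$center[2] + s$extent[2] / 2
    if (x0 < 0 || y0 < 0 || x1 > w_mm || y1 > h_mm) {
      stop(sprintf("geometry error: stain [%g, %g] x [%g, %g] mm outside the %g x %g mm scene",
                   x0, x1, y0, y1, w_mm, h_mm), call. = FALSE)
    }
  }
}

render_stack <- function(scene, protocol, stains, noise_stream) {
  h <- protocol$frame_height
  w <- protocol$frame_width
  nch <- nrow(protocol$channels)
  bg <- rep(scene$background_reflectance, length.out = nch)
  light_by_name <- stats::setNames(protocol$lights,
                                   vapply(protocol$lights, `[[`, "", "name"))
  filt_by_nm <- stats::setNames(
    protocol$filters,
    vapply(protocol$filters, function(f) as.character(f$center_wavelength), "")
  )
  masks <- lapply(stains, region_pixel_mask, height = h, width = w,
                  pixel_scale = scene$pixel_scale)
  frames <- vector("list", nch)
  for (i in seq_len(nch)) {
    ch <- protocol$channels[i, ]
    light <- light_by_name[[ch$light]]
    filt <- filt_by_nm[[as.character(ch$filter_nm)]]
    frame <- matrix(bg[i] + scene$leakage_gain * leakage_response(light, filt),
                    nrow = h, ncol = w)
    for (j in seq_along(stains)) {
      resp <- channel_response(stains[[j]]$fluor, light, filt) *
        stains[[j]]$concentration
      if (resp > 0) frame[masks[[j]]] <- frame[masks[[j]]] + resp
    }
    if (scene$noise_sd > 0) {
      frame <- frame + matrix(noise_stream(h * w, scene$noise_sd),
                              nrow = h, ncol = w)
    }
    frames[[i]] <- pmin(pmax(frame, 0), 1)
  }
  image_stack(frames, protocol$channels)
}

#' Render a registered dirty/clean phantom pair with ground truth
#'
#' Renders the scene once with its stains (dirty) and once with the stain
#' list emptied (clean), in perfect registration, plus the exact planted
#' pixel mask. Per channel, each pixel is background reflectance plus
#' excitation-light leak-through plus the summed fluorescence of covering
#' stains plus Gaussian noise, clipped to \[0, 1\]. Rendering is fully
#' deterministic given `scene$seed`; the global RNG state is left untouched.
#'
#' @param scene A [scene_spec()].
#' @param protocol An [make_protocol()] protocol.
#' @return List with elements `dirty` and `clean` ([image_stack()]s) and
#'   `truth` (a [stain_mask()] of the planted pixels).
#' @examples
#' p <- make_protocol(default_lights(), 480, 520, 20,
#'                    frame_width = 120, frame_height = 80)
#' pair <- render_pair(default_scene(p, noise_sd = 0), p)
#' sum(pair$truth$mask)  # 60 x 30 planted pixels
#' @export
render_pair <- function(scene, protocol) {
  stopifnot(inherits(scene, "scene_spec"),
            inherits(protocol, "acquisition_protocol"))
  check_scene_bounds(scene, protocol)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(scene$seed)
  noise_stream <- function(n, sd) stats::rnorm(n, 0, sd)
  dirty <- render_stack(scene, protocol, scene$stains, noise_stream)
  clean <- render_stack(scene, protocol, list(), noise_stream)
  truth <- matrix(FALSE, protocol$frame_height, protocol$frame_width)
  for (s in scene$stains) {
    if (s$concentration > 0) {
      truth <- truth | region_pixel_mask(s, protocol$frame_height,
                                         protocol$frame_width,
                                         scene$pixel_scale)
    }
  }
  list(dirty = dirty, clean = clean,
       truth = stain_mask(truth, source = "planted ground truth"))
}

#' Read a scene + protocol configuration from YAML
#'
#' One config file describes lights, the filter grid, frame size, stains,
#' noise and seed; see `inst/extdata/example_scene.yaml` for the schema.
#'
#' @param path YAML file path.
#' @return List with elements `scene` and `protocol`.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lights <- lapply(cfg$lights, function(l) {
    excitation_light(l$name, l$center_nm, l$i_rel,
                     bandwidth = l$bandwidth %||% 20)
  })
  protocol <- make_protocol(
    lights,
    filter_min = cfg$filters$min_nm, filter_max = cfg$filters$max_nm,
    increment = cfg$filters$increment_nm,
    frame_width = cfg$frame$width, frame_height = cfg$frame$height,
    passband_fwhm = cfg$filters$passband_fwhm %||% 10
  )
  stains <- lapply(cfg$stains %||% list(), function(s) {
    fl <- s$fluorophore %||% list()
    stain_region(
      shape = s$shape %||% "rectangle",
      center = unlist(s$center_mm), extent = unlist(s$extent_mm),
      fluor = fluorophore(
        name = fl$name %||% "flavin-like",
        excitation_peak = fl$excitation_peak %||% 450,
        excitation_width = fl$excitation_width %||% 60,
        emission_peak = fl$emission_peak %||% 500,
        emission_width = fl$emission_width %||% 25,
        quantum_scale = fl$quantum_scale %||% 30
      ),
      concentration = s$concentration %||% 1
    )
  })
  scene <- scene_spec(
    pixel_scale = cfg$pixel_scale_mm %||% 0.05,
    background_reflectance = cfg$background_reflectance %||% 0.2,
    stains = stains,
    noise_sd = cfg$noise_sd %||% 0.02,
    seed = cfg$seed %||% 0L,
    leakage_gain = cfg$leakage_gain %||% 1.2
  )
  list(scene = scene, protocol = protocol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
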