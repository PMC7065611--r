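#' Two-channel per-pixel features from labeled regions
#'
#' The manual clustering view: for each pixel of each named region, its
#' intensity under condition A (x-axis) and condition B (y-axis). The worked
#' armrest example uses green 525 nm at drive 50 vs red 625 nm at drive 255,
#' both through the 500 nm filter, on hand-picked stain and background crops.
#'
#' @param stack An [image_stack()].
#' @param cond_a,cond_b Length-2: `list(light, filter_nm)` or
#'   `c("green", 500)`.
#' @param regions Named list of [px_region()]s; names become point labels
#'   (e.g. `stain`, `background`).
#' @return Data frame with columns `a`, `b`, `row`, `col` (0-based pixel
#'   indices), `label`; attribute `conditions` records both channels.
#' @export
two_channel_features <- function(stack, cond_a, cond_b, regions) {
  if (is.null(names(regions)) || any(names(regions) == "")) {
    stop("regions must be a named list", call. = FALSE)
  }
  fa <- select_channel(stack, cond_a[[1]], as.numeric(cond_a[[2]]))
  fb <- select_channel(stack, cond_b[[1]], as.numeric(cond_b[[2]]))
  out <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    check_region_inside(r, stack$height, stack$width)
    rows <- r$y0 + seq_len(r$height)
    cols <- r$x0 + seq_len(r$width)
    grid <- expand.grid(row = rows, col = cols)
    data.frame(a = fa$frame[cbind(grid$row, grid$col)],
               b = fb$frame[cbind(grid$row, grid$col)],
               row = grid$row - 1L, col = grid$col - 1L,
               label = nm)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "conditions") <- list(a = c(cond_a[[1]], cond_a[[2]]),
                                  b = c(cond_b[[1]], cond_b[[2]]))
  res
}

#' Separation score between two labeled point groups
#'
#' Distance between group centroids divided by the pooled root-mean-square
#' within-group spread: a silhouette-like statistic quantifying how far one
#' cloud "clusters away" from the other. 0 for identical groups; capped at
#' `max_score` when the within-group spread vanishes but the centroids
#' differ.
#'
#' @param features A [two_channel_features()] data frame (or any data frame
#'   with numeric feature columns and a `label` column).
#' @param group_a,group_b Label values to compare.
#' @param max_score Cap for degenerate zero-spread separation.
#' @return Non-negative score.
#' @export
separation_score <- function(features, group_a, group_b, max_score = 1e6) {
  fcols <- setdiff(names(features), c("row", "col", "label"))
  xa <- as.matrix(features[features$label == group_a, fcols, drop = FALSE])
  xb <- as.matrix(features[features$label == group_b, fcols, drop = FALSE])
  if (nrow(xa) == 0 || nrow(xb) == 0) {
    stop("input error: both groups must be non-empty", call. = FALSE)
  }
  ca <- colMeans(xa)
  cb <- colMeans(xb)
  d <- sqrt(sum((ca - cb)^2))
  spread <- sqrt((sum(sweep(xa, 2, ca)^2) + sum(sweep(xb, 2, cb)^2)) /
                   (nrow(xa) + nrow(xb)))
  if (spread == 0) {
    if (d == 0) 0 else max_score
  } else {
    min(d / spread, max_score)
  }
}

#' Overlay cleaned-surface features onto the dirty-surface feature plot
#'
#' Combines the dirty-surface point cloud with the same regions measured
#' after cleaning; cleaned points are relabeled `cleaned-<label>`. On a
#' cleaned surface the former stain pixels fall back onto the background
#' cluster, which is the visual confirmation that the detected patch was
#' removable soil.
#'
#' @param features_dirty,features_clean [two_channel_features()] results
#'   computed with the same two conditions.
#' @return Combined feature data frame.
#' @export
cleaned_overlay <- function(features_dirty, features_clean) {
  if (is.null(features_clean) || nrow(features_clean) == 0) {
    stop("comparison error: cleaned feature set is empty", call. = FALSE)
  }
  ca <- attr(features_dirty, "conditions")
  cc <- attr(features_clean, "conditions")
  if (!identical(ca, cc)) {
    stop("comparison error: dirty and cleaned features use different conditions",
         call. = FALSE)
  }
  features_clean$label <- paste0("cleaned-", features_clean$label)
  out <- rbind(features_dirty, features_clean)
  attr(out, "conditions") <- ca
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# subsequent center drawn with probability proportional to squared distance
# to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j + 1, ] <- x[sample.int(n, 1, prob = d2), ]
      d2 <- pmin(d2, colSums((t(x) - centers[j + 1, ])^2))
    }
  }
  centers
}

#' Full-cube k-means stain segmentation
#'
#' The automatic counterpart to hand-picked thresholds: every pixel of the
#' region becomes a feature vector of its intensities across all channels
#' (all lights, all filters), and Lloyd's k-means with k-means++ seeding and
#' restarts partitions the pixels. The cluster with the higher mean raw
#' intensity in the designated emission channel (default green light, 500 nm
#' filter, the channel a flavin-like stain lights up) is called the stain.
#'
#' @param stack An [image_stack()] of the dirty surface.
#' @param region [px_region()] to segment.
#' @param k Number of clusters, >= 2 (default 2: stain vs background).
#' @param seed RNG seed for seeding/restarts; global RNG state is restored.
#' @param background_channel The emission channel used both to designate the
#'   stain cluster and as the grayscale base of [overlay_render()].
#' @param n_restarts k-means++ restarts; best objective wins.
#' @param iter_max Lloyd iteration cap.
#' @param scale_channels Standardize each channel to zero mean / unit
#'   variance within the region before clustering (default TRUE: unscaled
#'   cubes are dominated by high-drive channels); constant channels are
#'   dropped from the feature space.
#' @param stain_rule `"emission"` (default, the rule above) or `"minority"`
#'   (smallest cluster is the stain).
#' @return A `cluster_result`: `assignment` (integer matrix over the region,
#'   ids 1..k), `centroids` (k x channels, on the feature scale used),
#'   `stain_cluster`, `mask` (a [stain_mask()] over the region),
#'   `objective` (total within-cluster sum of squares), `k`, `seed`,
#'   `region`, `background_channel`.
#' @export
kmeans_cluster <- function(stack, region, k = 2, seed = 0L,
                           background_channel = c("green", 500),
                           n_restarts = 10, iter_max = 300,
                           scale_channels = TRUE,
                           stain_rule = c("emission", "minority")) {
  stain_rule <- match.arg(stain_rule)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  check_region_inside(region, stack$height, stack$width)
  sub <- crop(stack, region)
  x <- vapply(sub$frames, as.vector, numeric(region$width * region$height))
  if (nrow(unique(x)) < k) {
    stop("degenerate input: fewer than k distinct pixel feature vectors",
         call. = FALSE)
  }
  feat <- x
  if (scale_channels) {
    sds <- apply(x, 2, stats::sd)
    keep <- sds > 0
    feat <- scale(x[, keep, drop = FALSE])
    if (nrow(unique(feat)) < k) {
      stop("degenerate input: fewer than k distinct pixel feature vectors",
           call. = FALSE)
    }
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(feat, k)
    fit <- suppressWarnings(
      stats::kmeans(feat, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }

  emission <- select_channel(sub, background_channel[[1]],
                             as.numeric(background_channel[[2]]))
  raw_em <- as.vector(emission$frame)
  stain_id <- if (stain_rule == "emission") {
    means <- tapply(raw_em, best$cluster, mean)
    as.integer(names(means)[which.max(means)])
  } else {
    as.integer(names(which.min(table(best$cluster))))
  }
  assignment <- matrix(best$cluster, region$height, region$width)
  structure(
    list(assignment = assignment,
         centroids = best$centers,
         stain_cluster = stain_id,
         mask = stain_mask(assignment == stain_id,
                           source = sprintf("k-means k=%d seed=%d", k, seed)),
         objective = best$tot.withinss,
         k = as.integer(k), seed = as.integer(seed),
         region = region,
         background_channel = background_channel),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means result: k=%d, stain cluster %d (%d px), objective %.4g\n",
              x$k, x$stain_cluster, sum(x$mask$mask), x$objective))
  invisible(x)
}

#' Paint the stain cluster over a grayscale background frame
#'
#' @param result A [kmeans_cluster()] result (or any object with a `mask`),
#'   or a [stain_mask()].
#' @param background_frame Matrix in \[0, 1\] with the mask's dimensions.
#' @param highlight RGB triplet for stain pixels; default orange.
#' @return height x width x 3 RGB array in \[0, 1\].
#' @export
overlay_render <- function(result, background_frame,
                           highlight = c(1, 0.55, 0)) {
  m <- if (inherits(result, "stain_mask")) result$mask else result$mask$mask
  bg <- as_frame_matrix(background_frame)
  if (!all(dim(m) == dim(bg))) {
    stop("geometry error: mask and background dimensions differ",
         call. = FALSE)
  }
  out <- array(bg, dim = c(dim(bg), 3))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m] <- highlight[ch]
    out[, , ch] <- plane
  }
  out
}
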