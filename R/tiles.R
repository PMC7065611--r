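#' Square tiling of a region of interest
#'
#' Divides a region into disjoint square tiles, row-major. A right/bottom
#' remainder strip narrower than one tile is discarded with a warning.
#'
#' @param region A [px_region()].
#' @param tile_size_px Tile edge in px, >= 2. Default 10 px: 0.5 mm at the
#'   default 0.05 mm/px pixel scale, the crop size the manual clustering
#'   analysis works at.
#' @return A `tile_grid`: `region`, `tile_size`, `tiles` (list of
#'   [px_region()]s), `n_rows`, `n_cols`.
#' @export
make_grid <- function(region, tile_size_px = 10) {
  if (tile_size_px < 2) stop("tile_size_px must be >= 2", call. = FALSE)
  if (tile_size_px > region$width || tile_size_px > region$height) {
    stop("geometry error: tile larger than region", call. = FALSE)
  }
  n_cols <- region$width %/% tile_size_px
  n_rows <- region$height %/% tile_size_px
  if (n_cols * tile_size_px < region$width ||
      n_rows * tile_size_px < region$height) {
    warning(sprintf("discarding %d x %d px remainder strip not covered by %d px tiles",
                    region$width - n_cols * tile_size_px,
                    region$height - n_rows * tile_size_px, tile_size_px),
            call. = FALSE)
  }
  tiles <- vector("list", n_rows * n_cols)
  i <- 1L
  for (r in seq_len(n_rows)) {
    for (c_ in seq_len(n_cols)) {
      tiles[[i]] <- px_region(region$x0 + (c_ - 1L) * tile_size_px,
                              region$y0 + (r - 1L) * tile_size_px,
                              tile_size_px, tile_size_px)
      i <- i + 1L
    }
  }
  structure(list(region = region, tile_size = as.integer(tile_size_px),
                 tiles = tiles, n_rows = n_rows, n_cols = n_cols),
            class = "tile_grid")
}

#' Per-tile spectral summary features
#'
#' One vector per tile: mean intensity then intensity standard deviation for
#' every channel (length 2 x channels). A transparent stand-in feature recipe
#' isolated behind this one function so it can be swapped wholesale.
#'
#' @param stack An [image_stack()].
#' @param grid A [make_grid()] tiling inside the stack.
#' @return Numeric matrix, tiles x (2 x channels); columns named
#'   `mean_<light>_<filter>` / `sd_<light>_<filter>`.
#' @export
tile_features <- function(stack, grid) {
  check_region_inside(grid$region, stack$height, stack$width)
  meta <- stack$channel_meta
  cn <- c(sprintf("mean_%s_%d", meta$light, meta$filter_nm),
          sprintf("sd_%s_%d", meta$light, meta$filter_nm))
  nch <- length(stack$frames)
  out <- matrix(NA_real_, length(grid$tiles), 2 * nch,
                dimnames = list(NULL, cn))
  for (i in seq_along(grid$tiles)) {
    t <- grid$tiles[[i]]
    rows <- t$y0 + seq_len(t$height)
    cols <- t$x0 + seq_len(t$width)
    for (j in seq_len(nch)) {
      px <- stack$frames[[j]][rows, cols]
      out[i, j] <- mean(px)
      out[i, nch + j] <- stats::sd(px)
    }
  }
  out
}

#' Label grid tiles dirty/clean from a planted truth mask
#'
#' A tile is dirty when the planted stain covers at least `coverage` of its
#' pixels. The truth mask is in full-frame coordinates.
#'
#' @param grid A [make_grid()] tiling.
#' @param truth A [stain_mask()] or logical matrix (full frame).
#' @param coverage Fraction cutoff in (0, 1\]; default 0.5.
#' @return Character vector `"dirty"`/`"clean"`, one per tile.
#' @export
label_tiles <- function(grid, truth, coverage = 0.5) {
  m <- if (inherits(truth, "stain_mask")) truth$mask else truth
  vapply(grid$tiles, function(t) {
    rows <- t$y0 + seq_len(t$height)
    cols <- t$x0 + seq_len(t$width)
    if (mean(m[rows, cols]) >= coverage) "dirty" else "clean"
  }, "")
}

#' Train a linear max-margin tile classifier
#'
#' L2-regularized L2-loss (squared hinge) linear support vector machine,
#' minimizing `lambda/2 ||w||^2 + mean(max(0, 1 - y f(x))^2)` by BFGS from a
#' zero start: deterministic given the data and fully reproducible. Features
#' are standardized internally (training mean/sd kept in the model);
#' constant features are dropped.
#'
#' @param features Numeric matrix, tiles x features (see [tile_features()]).
#' @param labels Character/factor with exactly two values, `"dirty"` and
#'   `"clean"`; dirty is the positive class.
#' @param lambda L2 regularization strength.
#' @param seed Recorded in training metadata (training itself is
#'   deterministic).
#' @return A `tile_classifier` with `weights`, `bias`, `center`, `scale`,
#'   `keep` (feature columns used), `lambda`, `n`, `seed`, `converged`.
#' @export
svm_train <- function(features, labels, lambda = 1e-3, seed = 0L) {
  labels <- as.character(labels)
  if (!all(labels %in% c("dirty", "clean"))) {
    stop("labels must be 'dirty' or 'clean'", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("training error: both classes must be present", call. = FALSE)
  }
  if (min(table(labels)) < 2) {
    stop("training error: need >= 2 examples per class", call. = FALSE)
  }
  x <- as.matrix(features)
  y <- ifelse(labels == "dirty", 1, -1)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- which(scl > 0)
  xs <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  p <- length(keep)
  obj <- function(theta) {
    w <- theta[seq_len(p)]
    b <- theta[p + 1]
    marg <- 1 - y * (drop(xs %*% w) + b)
    lambda / 2 * sum(w^2) + mean(pmax(marg, 0)^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]
    b <- theta[p + 1]
    marg <- 1 - y * (drop(xs %*% w) + b)
    act <- pmax(marg, 0)
    gw <- lambda * w - 2 / length(y) * drop(crossprod(xs, act * y))
    gb <- -2 / length(y) * sum(act * y)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(
    list(weights = fit$par[seq_len(p)], bias = fit$par[p + 1],
         center = ctr[keep], scale = scl[keep], keep = keep,
         feature_names = colnames(x)[keep],
         lambda = lambda, n = length(y), seed = as.integer(seed),
         converged = fit$convergence == 0),
    class = "tile_classifier"
  )
}

#' Decision values and labels for tile feature vectors
#'
#' @param classifier A [svm_train()] model.
#' @param features Matrix with the training feature dimensionality.
#' @return List with `decision` (signed margin values; positive = dirty) and
#'   `label` (`"dirty"`/`"clean"`; a decision of exactly 0 is clean).
#' @export
svm_predict <- function(classifier, features) {
  x <- as.matrix(features)
  if (ncol(x) < max(classifier$keep)) {
    stop("input error: feature dimensionality does not match the classifier",
         call. = FALSE)
  }
  xs <- scale(x[, classifier$keep, drop = FALSE],
              center = classifier$center, scale = classifier$scale)
  dec <- drop(xs %*% classifier$weights) + classifier$bias
  list(decision = dec, label = ifelse(dec > 0, "dirty", "clean"))
}

#' Call a whole surface dirty or clean from its tiles
#'
#' Stains sit in small patches rather than spreading evenly, so on a dirty
#' surface dirty and clean tiles co-occur while a clean surface has none:
#' the surface is called dirty as soon as `min_dirty_tiles` tiles (default
#' 1) classify dirty.
#'
#' @param classifier A [svm_train()] model.
#' @param features Tile feature matrix for the surface.
#' @param min_dirty_tiles Dirty-tile count needed for a dirty call.
#' @return List with `tile_labels`, `surface_call` (`"dirty"`/`"clean"`),
#'   `dirty_fraction`, `n_tiles`.
#' @export
classify_surface <- function(classifier, features, min_dirty_tiles = 1) {
  pred <- svm_predict(classifier, features)
  n_dirty <- sum(pred$label == "dirty")
  list(tile_labels = pred$label,
       surface_call = if (n_dirty >= min_dirty_tiles) "dirty" else "clean",
       dirty_fraction = n_dirty / length(pred$label),
       n_tiles = length(pred$label))
}
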