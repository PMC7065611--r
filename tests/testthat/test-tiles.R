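test_that("tiling covers the region row-major, discarding remainders with a warning", {
  g <- make_grid(px_region(0, 0, 100, 100), 10)
  expect_length(g$tiles, 100)
  expect_equal(g$tiles[[1]][c("x0", "y0")], list(x0 = 0L, y0 = 0L))
  expect_equal(g$tiles[[2]][c("x0", "y0")], list(x0 = 10L, y0 = 0L))
  # disjoint cover: every region pixel in exactly one tile
  hits <- matrix(0L, 100, 100)
  for (t in g$tiles) {
    hits[t$y0 + seq_len(t$height), t$x0 + seq_len(t$width)] <-
      hits[t$y0 + seq_len(t$height), t$x0 + seq_len(t$width)] + 1L
  }
  expect_true(all(hits == 1L))
  expect_warning(g2 <- make_grid(px_region(0, 0, 105, 100), 10),
                 "remainder")
  expect_length(g2$tiles, 100)
  expect_error(make_grid(px_region(0, 0, 10, 10), 20), "geometry error")
  expect_error(make_grid(px_region(0, 0, 10, 10), 1), ">= 2")
})

test_that("tile features are per-channel means and SDs", {
  flat <- image_stack(list(matrix(0.3, 20, 20), matrix(0.7, 20, 20)),
                      data.frame(light = c("green", "red"),
                                 light_nm = c(525, 625),
                                 i_rel = c(50L, 255L), filter_nm = 500L))
  ft <- tile_features(flat, make_grid(px_region(0, 0, 20, 20), 10))
  expect_equal(dim(ft), c(4, 4))  # 2 x channels columns
  expect_true(all(ft[, 1] == 0.3 & ft[, 2] == 0.7))
  expect_true(all(ft[, 3:4] == 0))

  pair <- fig2_pair(noise_sd = 0)
  ft2 <- tile_features(pair$dirty,
                       make_grid(stain_crop_region(), 10))
  expect_equal(ncol(ft2), 2 * n_channels(pair$dirty))
  grid <- make_grid(stain_crop_region(), 10)
  labs <- label_tiles(grid, pair$truth)
  in_mean <- ft2[labs == "dirty", "mean_green_500"]
  out_mean <- ft2[labs == "clean", "mean_green_500"]
  expect_gt(min(in_mean), max(out_mean))
})

test_that("max-margin training separates clouds and is symmetric under label flips", {
  set.seed(8)
  n <- 40
  x <- rbind(matrix(rnorm(2 * n, 0, 0.5), n, 2),
             matrix(rnorm(2 * n, 3, 0.5), n, 2))
  y <- rep(c("clean", "dirty"), each = n)
  m <- svm_train(x, y, lambda = 1e-3)
  expect_true(m$converged)
  expect_equal(svm_predict(m, x)$label, y)  # separable: zero training error
  m_flip <- svm_train(x, ifelse(y == "dirty", "clean", "dirty"),
                      lambda = 1e-3)
  expect_equal(m_flip$weights, -m$weights, tolerance = 1e-4)
  expect_equal(m_flip$bias, -m$bias, tolerance = 1e-4)
  # duplicating every training point leaves the decision unchanged
  m_dup <- svm_train(rbind(x, x), c(y, y), lambda = 1e-3)
  expect_equal(svm_predict(m_dup, x)$label, svm_predict(m, x)$label)
  expect_equal(svm_predict(m_dup, x)$decision, svm_predict(m, x)$decision,
               tolerance = 0.05)
  expect_error(svm_train(x, rep("clean", 2 * n)), "training error")
  expect_error(svm_train(x[c(1, 41:80), ], y[c(1, 41:80)]), "training error")
})

test_that("surface call: any dirty tile makes the surface dirty", {
  set.seed(9)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 3, 0.3), 20, 2))
  y <- rep(c("clean", "dirty"), each = 20)
  m <- svm_train(x, y)
  all_clean <- matrix(rnorm(20, 0, 0.3), 10, 2)
  res <- classify_surface(m, all_clean)
  expect_equal(res$surface_call, "clean")
  expect_equal(res$dirty_fraction, 0)
  mixed <- rbind(all_clean, matrix(3, 3, 2))
  res2 <- classify_surface(m, mixed)
  expect_equal(res2$surface_call, "dirty")
  expect_equal(res2$dirty_fraction, 3 / 13)
  # configurable minimum dirty-tile count
  expect_equal(classify_surface(m, mixed, min_dirty_tiles = 5)$surface_call,
               "clean")
})

test_that("noise-free phantom: tile labels match planted geometry and dirty fraction is monotone in stain area", {
  pair <- fig2_pair(noise_sd = 0)
  grid <- make_grid(stain_crop_region(), 10)
  labs <- label_tiles(grid, pair$truth)
  feats <- tile_features(pair$dirty, grid)
  feats_clean <- tile_features(pair$clean, grid)
  m <- svm_train(rbind(feats, feats_clean),
                 c(labs, rep("clean", nrow(feats_clean))))
  res <- classify_surface(m, feats)
  expect_equal(res$surface_call, "dirty")
  expect_equal(res$tile_labels, unname(labs))
  expect_equal(classify_surface(m, feats_clean)$surface_call, "clean")

  # growing the planted stain never shrinks the labeled dirty fraction
  p <- small_protocol()
  fractions <- vapply(c(1, 2, 3), function(len_mm) {
    sc <- scene_spec(stains = list(
      stain_region("rectangle", center = c(5, 3.75),
                   extent = c(len_mm, 1.5))), noise_sd = 0)
    pr <- render_pair(sc, p)
    mean(label_tiles(grid, pr$truth) == "dirty")
  }, numeric(1))
  expect_true(all(diff(fractions) >= 0))
})
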