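make_regions <- function() {
  list(stain = px_region(85, 65, 10, 10),       # inside the planted stain
       background = px_region(10, 10, 10, 10))  # far from it
}

test_that("two-channel features carry one labeled vector per region pixel", {
  pair <- fig2_pair(noise_sd = 0.01, seed = 3L)
  ft <- two_channel_features(pair$dirty, c("green", 500), c("red", 500),
                             make_regions())
  expect_equal(nrow(ft), 200)
  expect_equal(as.vector(table(ft$label)), c(100, 100))
  # stain points sit higher on the green-excited 500 nm axis
  expect_gt(min(ft$a[ft$label == "stain"]),
            max(ft$a[ft$label == "background"]))
  # duplicated axis puts every point on the diagonal
  dup <- two_channel_features(pair$dirty, c("green", 500), c("green", 500),
                              make_regions())
  expect_equal(dup$a, dup$b)
  expect_error(
    two_channel_features(pair$dirty, c("green", 505), c("red", 500),
                         make_regions()),
    "lookup error")
})

test_that("separation score: zero when identical, capped when degenerate, large at 5 sigma", {
  pts <- data.frame(a = rep(c(0.1, 0.2), each = 5),
                    b = rep(c(0.3, 0.4), each = 5),
                    label = "x")
  same <- rbind(transform(pts, label = "g1"), transform(pts, label = "g2"))
  expect_equal(separation_score(same, "g1", "g2"), 0)
  masses <- data.frame(a = rep(c(0, 1), each = 3), b = 0,
                       label = rep(c("g1", "g2"), each = 3))
  expect_equal(separation_score(masses, "g1", "g2"), 1e6)
  expect_error(separation_score(masses, "g1", "nope"), "input error")

  lv <- green500_levels()
  pair <- fig2_pair(noise_sd = lv$gap / 5, seed = 5L)
  ft <- two_channel_features(pair$dirty, c("green", 500), c("red", 500),
                             make_regions())
  expect_gt(separation_score(ft, "stain", "background"), 2)
})

test_that("cleaned-surface points rejoin the background cluster", {
  pair <- fig2_pair(noise_sd = 0, seed = 0L)
  conds <- list(c("green", 500), c("red", 500))
  fd <- two_channel_features(pair$dirty, conds[[1]], conds[[2]],
                             make_regions())
  fc <- two_channel_features(pair$clean, conds[[1]], conds[[2]],
                             make_regions())
  comb <- cleaned_overlay(fd, fc)
  cen <- function(lbl) colMeans(comb[comb$label == lbl, c("a", "b")])
  # noise-free: cleaned stain area is identical to background
  expect_equal(cen("cleaned-stain"), cen("background"))
  d_dirty <- sqrt(sum((cen("stain") - cen("background"))^2))
  d_clean <- sqrt(sum((cen("cleaned-stain") - cen("background"))^2))
  expect_gt(d_dirty, d_clean)
  # mismatched conditions and empty clean sets are comparison errors
  fc2 <- two_channel_features(pair$clean, conds[[1]], c("red", 520),
                              make_regions())
  expect_error(cleaned_overlay(fd, fc2), "comparison error")
  expect_error(cleaned_overlay(fd, fd[0, ]), "comparison error")
})

test_that("k-means recovers the planted stain exactly on noise-free phantoms", {
  pair <- fig2_pair(noise_sd = 0)
  region <- stain_crop_region()
  km <- kmeans_cluster(pair$dirty, region, k = 2, seed = 0L)
  expect_equal(jaccard(km$mask, crop_truth(pair)), 1)
  # determinism under a fixed seed
  km2 <- kmeans_cluster(pair$dirty, region, k = 2, seed = 0L)
  expect_identical(km$assignment, km2$assignment)
  expect_identical(km$stain_cluster, km2$stain_cluster)
  # stain designation is invariant to the arbitrary cluster ids a different
  # seeding produces
  km3 <- kmeans_cluster(pair$dirty, region, k = 2, seed = 99L)
  expect_identical(km$mask$mask, km3$mask$mask)
})

test_that("degenerate regions are rejected", {
  flat <- image_stack(list(matrix(0.5, 10, 10), matrix(0.2, 10, 10)),
                      data.frame(light = c("green", "red"), light_nm = c(525, 625),
                                 i_rel = c(50L, 255L), filter_nm = 500L))
  expect_error(kmeans_cluster(flat, px_region(0, 0, 10, 10), k = 2),
               "degenerate input")
  pair <- fig2_pair(noise_sd = 0)
  expect_error(kmeans_cluster(pair$dirty, stain_crop_region(), k = 1),
               "k must be >= 2")
})

test_that("k-means objective matches exhaustive 2-partition enumeration on 12 points", {
  set.seed(31)
  n <- 12
  f1 <- matrix(runif(n), 3, 4)
  f2 <- matrix(runif(n), 3, 4)
  tiny <- image_stack(list(f1, f2),
                      data.frame(light = c("green", "red"),
                                 light_nm = c(525, 625),
                                 i_rel = c(50L, 255L), filter_nm = 500L))
  km <- kmeans_cluster(tiny, px_region(0, 0, 4, 3), k = 2, seed = 0L,
                       n_restarts = 50)
  # independent oracle: enumerate every 2-partition of the standardized
  # feature vectors and take the minimum within-cluster sum of squares
  x <- scale(cbind(as.vector(f1), as.vector(f2)))
  wss <- function(m) if (nrow(m) == 0) 0 else
    sum(sweep(m, 2, colMeans(m))^2)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    inA <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    best <- min(best, wss(x[inA, , drop = FALSE]) +
                  wss(x[!inA, , drop = FALSE]))
  }
  expect_equal(km$objective, best, tolerance = 1e-8)
})

test_that("overlay painting highlights exactly the stain cluster", {
  pair <- fig2_pair(noise_sd = 0)
  region <- stain_crop_region()
  km <- kmeans_cluster(pair$dirty, region, k = 2, seed = 0L)
  bg <- select_channel(crop(pair$dirty, region), "green", 500)$frame
  img <- overlay_render(km, bg)
  expect_equal(dim(img), c(region$height, region$width, 3))
  hot <- img[, , 1] == 1 & img[, , 3] == 0
  expect_identical(hot, km$mask$mask)
  # an empty mask leaves the grayscale background untouched
  none <- stain_mask(matrix(FALSE, region$height, region$width), "none")
  img0 <- overlay_render(none, bg)
  for (ch in 1:3) expect_equal(img0[, , ch], bg, ignore_attr = TRUE)
  expect_error(overlay_render(none, bg[1:10, ]), "geometry error")
})
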