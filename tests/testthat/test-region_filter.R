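# Region features, rule-based rejection and ellipse standardization.

test_that("a filled disk is solid with zero mass displacement", {
  msk <- paint_disk(matrix(0, 50, 50), 25, 25, 20, 1) > 0
  pre <- matrix(100, 50, 50)
  ft <- compute_region_features(which(msk), pre, 3)
  expect_gte(ft$s, 0.95)
  expect_lt(ft$d, 1e-6)
  expect_equal(ft$area, sum(msk))
})

test_that("solidity reproduces the standard region-properties values", {
  # frozen from an independent implementation (scikit-image regionprops)
  sol <- function(r) {
    msk <- paint_disk(matrix(0, 2 * r + 9, 2 * r + 9), r + 5, r + 5, r, 1) > 0
    ft <- compute_region_features(which(msk), matrix(100, 2 * r + 9, 2 * r + 9), 3)
    ft$s
  }
  expect_equal(sol(10), 0.9296188, tolerance = 1e-6)
  expect_equal(sol(12), 0.9483871, tolerance = 1e-6)
})

test_that("boundary saliency equals the exact band medians on a disk fixture", {
  img <- paint_disk(matrix(200, 60, 60), 30, 30, 10, 50)
  msk <- paint_disk(matrix(0, 60, 60), 30, 30, 10, 1) > 0
  ft <- compute_region_features(which(msk), img, 3)
  expect_equal(ft$l, 150)
})

test_that("a cross-shaped region fails the solidity range", {
  msk <- matrix(FALSE, 40, 40)
  msk[16:24, 8:32] <- TRUE
  msk[8:32, 16:24] <- TRUE
  ft <- compute_region_features(which(msk), matrix(100, 40, 40), 3)
  expect_lt(ft$s, 0.875)
})

test_that("a region with no outside band has undefined saliency and is rejected", {
  full <- matrix(TRUE, 12, 12)
  ft <- compute_region_features(which(full), matrix(80, 12, 12), 3)
  expect_true(is.na(ft$l))
  df <- data.frame(s = 0.95, l = ft$l, d = 0.01, area = 400)
  expect_false(filter_candidates(df, 10))
})

test_that("filter_candidates applies the printed ranges with their open/closed senses", {
  # s = 0.9, l = 100, d = 0.05, area = 500 at n = 10: inside every range
  expect_true(filter_candidates(
    data.frame(s = 0.9, l = 100, d = 0.05, area = 500), 10))
  # area below n^2 pi ~ 314.2
  expect_false(filter_candidates(
    data.frame(s = 0.9, l = 100, d = 0.05, area = 250), 10))
  # s at or below 0.875 fails regardless of the rest
  expect_false(filter_candidates(
    data.frame(s = 0.87, l = 100, d = 0.05, area = 500), 10))
  expect_false(filter_candidates(
    data.frame(s = 0.875, l = 100, d = 0.05, area = 500), 10))
  # boundary senses: l = 20 open; d = 0.08 closed; area bounds closed
  expect_false(filter_candidates(
    data.frame(s = 0.9, l = 20, d = 0.05, area = 500), 10))
  expect_true(filter_candidates(
    data.frame(s = 0.9, l = 100, d = 0.08, area = 500), 10))
  expect_true(filter_candidates(
    data.frame(s = 0.9, l = 100, d = 0, area = ceiling(100 * pi)), 10))
  expect_false(filter_candidates(
    data.frame(s = 0.9, l = 100, d = 0.081, area = 500), 10))
})

test_that("filtering is order-independent", {
  set.seed(31)
  df <- data.frame(s = runif(30, 0.8, 1), l = runif(30, 0, 60),
                   d = runif(30, 0, 0.15), area = runif(30, 200, 1400))
  keep <- filter_candidates(df, 10)
  perm <- sample(30)
  expect_identical(filter_candidates(df[perm, ], 10), keep[perm])
})

test_that("every region accepted by the filter satisfies all four ranges (fuzzed)", {
  set.seed(57)
  for (n in c(10L, 14L, 18L)) {
    df <- data.frame(s = runif(200, 0.7, 1.0), l = runif(200, -40, 300),
                     d = runif(200, 0, 0.2), area = runif(200, 100, 5000))
    acc <- df[filter_candidates(df, n), ]
    if (nrow(acc) == 0) next
    expect_true(all(acc$s > 0.875 & acc$s < 1))
    expect_true(all(acc$l > 20 & acc$l < 255))
    expect_true(all(acc$d >= 0 & acc$d <= 0.08))
    expect_true(all(acc$area >= n^2 * pi & acc$area <= 4 * n^2 * pi))
  }
})

test_that("moment ellipses recover disks and axis-aligned ellipses", {
  dsk <- paint_disk(matrix(0, 40, 40), 20, 20, 12, 1) > 0
  e <- fit_ellipse(which(dsk), 40)
  expect_equal(e$a, 12, tolerance = 0.5 / 12)
  expect_equal(e$b, 12, tolerance = 0.5 / 12)
  expect_equal(c(e$cx, e$cy), c(19, 19), tolerance = 0.01)

  ell <- rasterize_ellipse(list(cx = 30, cy = 25, a = 18, b = 10, theta = 0),
                           c(60, 70))
  f <- fit_ellipse(ell, 60)
  expect_equal(f$a, 18, tolerance = 0.5 / 18)
  expect_equal(f$b, 10, tolerance = 0.5 / 10)
  expect_lt(min(f$theta, pi - f$theta), 3 * pi / 180)

  expect_error(fit_ellipse(1:4, 40), "5 pixels")
  # collinear pixels are degenerate
  expect_error(fit_ellipse(c(5, 15, 25, 35, 45) * 40 + 3, 40), "degenerate")
})

test_that("ellipse fitting is equivariant under a quarter-turn of the grid", {
  px <- rasterize_ellipse(list(cx = 25, cy = 20, a = 15, b = 8,
                               theta = pi / 6), c(50, 50))
  e1 <- fit_ellipse(px, 50)
  # rotate the pixel set 90 degrees: (r, c) -> (c, nr + 1 - r)
  rc <- cbind((px - 1L) %% 50L + 1L, (px - 1L) %/% 50L + 1L)
  px2 <- (50L + 1L - rc[, 1L] - 1L) * 50L + rc[, 2L]
  e2 <- fit_ellipse(px2, 50)
  expect_equal(e2$a, e1$a, tolerance = 1e-9)
  expect_equal(e2$b, e1$b, tolerance = 1e-9)
  expect_equal((e1$theta + pi / 2) %% pi, e2$theta, tolerance = 1e-9)
})

test_that("rasterized ellipse area tracks the analytic area", {
  for (ab in list(c(12, 12), c(18, 10), c(15, 11))) {
    px <- rasterize_ellipse(list(cx = 40, cy = 40, a = ab[1], b = ab[2],
                                 theta = 0.7), c(80, 80))
    expect_equal(length(px), pi * ab[1] * ab[2], tolerance = 0.05)
  }
})
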