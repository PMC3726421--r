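# Marker extraction, minima imposition and marker-controlled watershed.

test_that("minima imposition leaves minima exactly at the marker pixels", {
  set.seed(3)
  for (i in 1:5) {
    f <- rand_img(20, 20, 8)
    mask <- matrix(FALSE, 20, 20)
    mask[cbind(sample(2:19, 3), sample(2:19, 3))] <- TRUE
    imp <- impose_minima(f, mask)
    rm <- regional_minima(imp)
    expect_identical(canon_labels(rm > 0), canon_labels(mask))
  }
  expect_error(impose_minima(rand_img(5, 5), matrix(FALSE, 5, 5)), "empty")
})

test_that("regional-minima markers exclude border plateaus and oversized components", {
  # uniform image: the whole-frame minimum is excluded
  flat <- preprocess_at_scale(matrix(10, 64, 64), 10)
  expect_equal(max(extract_minima_markers(flat, 10)), 0L)

  # two interior dark disks -> 2 markers; one disk -> 1 marker
  img <- matrix(200, 90, 90)
  img <- paint_disk(img, 30, 30, 6, 50)
  img <- paint_disk(img, 60, 60, 6, 50)
  expect_equal(max(extract_minima_markers(img, 10)), 2L)
  one <- paint_disk(matrix(200, 64, 64), 32, 32, 6, 50)
  expect_equal(max(extract_minima_markers(one, 10)), 1L)

  # a minimum touching the border is dropped
  img2 <- matrix(200, 64, 64)
  img2[1:4, 10:14] <- 50
  img2 <- paint_disk(img2, 40, 40, 5, 50)
  expect_equal(max(extract_minima_markers(img2, 10)), 1L)
})

test_that("background markers are thin, disjoint skeletons that separate markers", {
  fg <- matrix(0L, 120, 120)
  fg[60, 60] <- 1L
  n <- 10L
  sk <- build_background_marker(fg, n)
  expect_true(any(sk))
  dil <- nucseg:::cpp_binary_dilate_disk(fg > 0, 2 * n)
  expect_false(any(sk & dil))

  # two markers 5n apart: the skeleton separates their dilated disks
  fg2 <- matrix(0L, 140, 140)
  fg2[70, 40] <- 1L; fg2[70, 90] <- 2L
  sk2 <- build_background_marker(fg2, n)
  comp <- o_label(!sk2, conn = 4)
  expect_true(comp[70, 40] != comp[70, 90])

  expect_error(build_background_marker(matrix(0L, 20, 20), 5), "at least one")
  dense <- matrix(0L, 30, 30); dense[15, 15] <- 1L
  expect_error(build_background_marker(dense, 11), "dense")
})

test_that("marker sets validate disjointness and marker types", {
  fg <- matrix(0L, 10, 10); fg[5, 5] <- 1L
  bg <- matrix(FALSE, 10, 10); bg[1, ] <- TRUE
  ms <- marker_set(fg, bg, "frst", 4)
  expect_s3_class(ms, "marker_set")
  bad <- bg; bad[5, 5] <- TRUE
  expect_error(marker_set(fg, bad, "frst", 4), "overlap")
  expect_error(marker_set(fg, matrix(FALSE, 10, 10), "frst", 4), "empty")
})

test_that("watershed yields one region per marker containing that marker (fuzzed)", {
  set.seed(17)
  for (trial in 1:40) {
    nr <- sample(24:40, 1); nc <- sample(24:40, 1)
    img <- rand_img(nr, nc, 12)
    k <- sample(1:4, 1)
    fg <- matrix(0L, nr, nc)
    pts <- cbind(sample(4:(nr - 3), k), sample(4:(nc - 3), k))
    pts <- pts[!duplicated(pts), , drop = FALSE]
    for (i in seq_len(nrow(pts))) fg[pts[i, 1], pts[i, 2]] <- i
    bg <- matrix(FALSE, nr, nc)
    bg[1, ] <- TRUE   # frame edge as background marker
    bg[fg > 0] <- FALSE
    ms <- marker_set(fg, bg, "minima", 5)
    lab <- watershed_with_markers(img, ms)
    expect_equal(sort(unique(lab[lab > 0])), seq_len(nrow(pts)))
    for (i in seq_len(nrow(pts))) expect_equal(lab[pts[i, 1], pts[i, 2]], i)
  }
})

test_that("a marked dark disk is recovered almost entirely by its region", {
  img <- paint_disk(matrix(200, 80, 80), 40, 40, 14, 60)
  fg <- matrix(0L, 80, 80); fg[40, 40] <- 1L
  ms <- marker_set(fg, build_background_marker(fg, 7), "frst", 7)
  lab <- watershed_with_markers(img, ms)
  disk <- which(paint_disk(matrix(0, 80, 80), 40, 40, 14, 1) > 0)
  expect_gte(sum(lab[disk] == 1L) / length(disk), 0.8)
})

test_that("touching disks split along the tangent chord", {
  img <- matrix(200, 80, 100)
  img <- paint_disk(img, 40, 38, 12, 60)
  img <- paint_disk(img, 40, 62, 12, 60)
  fg <- matrix(0L, 80, 100); fg[40, 38] <- 1L; fg[40, 62] <- 2L
  ms <- marker_set(fg, build_background_marker(fg, 6), "frst", 6)
  lab <- watershed_with_markers(img, ms)
  expect_equal(max(lab), 2L)
  w1 <- which(lab == 1L, arr.ind = TRUE)
  w2 <- which(lab == 2L, arr.ind = TRUE)
  # tangent chord is the vertical line x = 50
  expect_true(all(w1[, 2] <= 52))
  expect_true(all(w2[, 2] >= 48))
})

test_that("foreground regions and the background partition the non-ridge pixels", {
  img <- matrix(200, 60, 60)
  img <- paint_disk(img, 20, 20, 8, 70)
  img <- paint_disk(img, 42, 40, 8, 70)
  fg <- matrix(0L, 60, 60); fg[20, 20] <- 1L; fg[42, 40] <- 2L
  bgm <- build_background_marker(fg, 5)
  ms <- marker_set(fg, bgm, "frst", 5)
  grad <- nucseg:::sobel_magnitude(img)
  seeds <- fg; seeds[bgm] <- 3L
  lab_all <- nucseg:::cpp_watershed(impose_minima(grad, seeds > 0), seeds)
  expect_setequal(unique(as.vector(lab_all)), c(0L, 1L, 2L, 3L))
  # ridge pixels are a thin minority
  expect_lt(mean(lab_all == 0L), 0.05)
})
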