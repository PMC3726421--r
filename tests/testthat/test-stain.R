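# Lambert-Beer optical-density conversion, stain unmixing and the
# re-rendered hematoxylin grayscale image.

test_that("optical density maps background to zero and black to the clamp ceiling", {
  tile <- array(255, c(4, 4, 3))
  expect_equal(rgb_to_optical_density(tile), array(0, c(4, 4, 3)))

  black <- array(0, c(2, 2, 3))
  od <- rgb_to_optical_density(black)
  expect_equal(unique(as.vector(od)), -log10(1 / 255))
})

test_that("forward-composed optical densities are recovered within quantization", {
  sv <- stain_vectors()
  set.seed(42)
  h <- matrix(runif(100, 0, 0.8), 10, 10)
  e <- matrix(runif(100, 0, 0.5), 10, 10)
  tile <- nucseg:::render_he_tile(h, e, sv)
  od <- rgb_to_optical_density(tile, sv$i0)
  truth <- array(0, dim(od))
  for (ch in 1:3)
    truth[, , ch] <- sv$M[ch, "hematoxylin"] * h + sv$M[ch, "eosin"] * e
  # OD error from rounding intensities to integers: 0.5 / (I ln 10) per pixel
  for (ch in 1:3) {
    intens <- pmax(tile[, , ch], 1)
    tol <- 0.6 / (intens * log(10))
    expect_true(all(abs(od[, , ch] - truth[, , ch]) <= tol))
  }
})

test_that("rgb_to_optical_density validates input", {
  expect_error(rgb_to_optical_density(matrix(0, 3, 3)), "3")
  expect_error(rgb_to_optical_density(array(300, c(2, 2, 3))), "255")
})

test_that("unmixing inverts the stain matrix exactly on clean inputs", {
  sv <- stain_vectors()
  od0 <- array(0, c(3, 3, 3))
  conc <- unmix_stains(od0, sv)
  expect_equal(conc$hematoxylin, matrix(0, 3, 3))
  expect_equal(conc$eosin, matrix(0, 3, 3))

  od1 <- array(0, c(1, 1, 3))
  od1[1, 1, ] <- sv$M[, "hematoxylin"] * 1.0
  conc1 <- unmix_stains(od1, sv)
  expect_equal(conc1$hematoxylin[1, 1], 1.0, tolerance = 1e-10)
  expect_equal(conc1$eosin[1, 1], 0.0, tolerance = 1e-10)
})

test_that("unmixing is linear before clipping", {
  sv <- stain_vectors()
  set.seed(7)
  od1 <- array(runif(27), c(3, 3, 3))
  od2 <- array(runif(27), c(3, 3, 3))
  u1 <- unmix_stains(od1, sv, clip = FALSE)
  u2 <- unmix_stains(od2, sv, clip = FALSE)
  u12 <- unmix_stains(2 * od1 + 3 * od2, sv, clip = FALSE)
  expect_equal(u12$hematoxylin, 2 * u1$hematoxylin + 3 * u2$hematoxylin,
               tolerance = 1e-12)
  expect_equal(u12$eosin, 2 * u1$eosin + 3 * u2$eosin, tolerance = 1e-12)
})

test_that("rendered concentration fields round-trip with correlation > 0.99", {
  sv <- stain_vectors()
  set.seed(11)
  h <- matrix(runif(2500, 0, 1), 50, 50)
  e <- matrix(runif(2500, 0, 0.6), 50, 50)
  tile <- nucseg:::render_he_tile(h, e, sv)
  conc <- unmix_stains(rgb_to_optical_density(tile, sv$i0), sv)
  expect_gt(cor(as.vector(h), as.vector(conc$hematoxylin)), 0.99)
  expect_gt(cor(as.vector(e), as.vector(conc$eosin)), 0.99)
})

test_that("hematoxylin grayscale image has the stated polarity and range", {
  sv <- stain_vectors()
  white <- array(255, c(8, 8, 3))
  expect_equal(hematoxylin_image(white, sv), matrix(255, 8, 8))

  # nucleus disk with high hematoxylin: interior much darker than surround
  h <- matrix(0, 40, 40)
  h <- paint_disk(h, 20, 20, 8, 0.8)
  e <- matrix(0.3, 40, 40)
  tile <- nucseg:::render_he_tile(h, e, sv)
  hi <- hematoxylin_image(tile, sv)
  expect_gt(hi[1, 1] - hi[20, 20], 50)

  # eosin-only tile stays within a few gray levels of white
  t2 <- nucseg:::render_he_tile(matrix(0, 10, 10), matrix(0.5, 10, 10), sv)
  h2 <- hematoxylin_image(t2, sv)
  expect_lt(max(255 - h2), 5)
})

test_that("more hematoxylin never brightens a pixel", {
  sv <- stain_vectors()
  cs <- seq(0, 1.5, by = 0.05)
  vals <- sapply(cs, function(cc)
    nucseg:::render_stain_gray(matrix(cc, 1, 1), sv$M[, "hematoxylin"], sv$i0)[1, 1])
  expect_true(all(diff(vals) <= 0))
})

test_that("stain vector construction enforces its invariants", {
  sv <- stain_vectors()
  expect_equal(unname(colSums(sv$M^2)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(sv$M >= 0))
  expect_gt(abs(det(sv$M)), 1e-8)
  expect_error(stain_vectors(hematoxylin = c(1, 0, 0), eosin = c(1, 0, 0)),
               "collinear")
  expect_error(stain_vectors(hematoxylin = c(-1, 1, 0)), "non-negative")
})
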