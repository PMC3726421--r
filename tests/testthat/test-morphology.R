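# Reconstruction-based morphology, h-minima, regional minima, skeleton.

test_that("opening/closing by reconstruction match the geodesic oracle on fixtures", {
  flat <- matrix(5, 20, 20)
  expect_equal(reconstruct_open(flat, 3), flat)
  expect_equal(reconstruct_close(flat, 3), flat)

  # small bright square on dark background is flattened away
  img <- matrix(100, 40, 40)
  img[18:21, 18:21] <- 200
  ro <- reconstruct_open(img, 5)
  expect_equal(ro, matrix(100, 40, 40))
  expect_equal(ro, o_reconstruct_dil(erode_disk(img, 5), img))

  # bright object wider than the SE keeps its plateau
  img2 <- matrix(100, 40, 40)
  img2 <- paint_disk(img2, 20, 20, 9, 200)
  ro2 <- reconstruct_open(img2, 5)
  expect_equal(max(ro2), 200)
  expect_equal(ro2, o_reconstruct_dil(erode_disk(img2, 5), img2))

  # dual: small dark speckle removed, large dark blob kept
  img3 <- matrix(200, 40, 40)
  img3[10:11, 10:11] <- 50
  expect_equal(reconstruct_close(img3, 4), matrix(200, 40, 40))
  img4 <- paint_disk(matrix(200, 40, 40), 20, 20, 10, 50)
  rc4 <- reconstruct_close(img4, 4)
  expect_equal(min(rc4), 50)
  expect_equal(rc4, o_reconstruct_ero(dilate_disk(img4, 4), img4))
})

test_that("reconstruction operators are idempotent and ordered around the identity", {
  set.seed(5)
  for (i in 1:5) {
    img <- rand_img(24, 24, 8)
    op <- reconstruct_open(img, 3)
    cl <- reconstruct_close(img, 3)
    expect_true(all(op <= img + 1e-12))
    expect_true(all(cl >= img - 1e-12))
    expect_equal(reconstruct_open(op, 3), op)
    expect_equal(reconstruct_close(cl, 3), cl)
  }
})

test_that("oversized structuring elements are rejected", {
  expect_error(erode_disk(matrix(0, 10, 10), 6), "exceeds")
  expect_error(reconstruct_open(matrix(0, 10, 10), 8), "exceeds")
})

test_that("preprocessing at a scale flattens sub-scale detail and tags the scale", {
  flat <- matrix(7, 64, 64)
  out <- preprocess_at_scale(flat, 10)
  expect_equal(unclass(out), flat, ignore_attr = TRUE)
  expect_identical(attr(out, "scale"), 10L)

  # bright speckles inside a dark nucleus are removed at n = 10
  img <- matrix(200, 64, 64)
  img <- paint_disk(img, 32, 32, 14, 60)
  img[30:32, 30:32] <- 110   # speckle of diameter 3 < n
  pre <- preprocess_at_scale(img, 10)
  inside <- paint_disk(matrix(0, 64, 64), 32, 32, 10, 1) > 0
  expect_lt(diff(range(pre[inside])), 5)

  expect_error(preprocess_at_scale(img, 1), ">= 2")
})

test_that("a thin dark protrusion is removed by the final closing", {
  img <- matrix(200, 64, 64)
  img <- paint_disk(img, 32, 32, 12, 60)
  img[31:33, 44:54] <- 60    # 3-px-wide protrusion, << n/2 = 5
  pre <- preprocess_at_scale(img, 10)
  expect_gt(min(pre[31:33, 50:54]), 150)
})

test_that("h-minima transform obeys its definition and bounds", {
  prof <- matrix(1, 1, 30)
  prof[1, 5:8] <- 0.7    # depth 0.3
  prof[1, 20:23] <- 0.5  # depth 0.5
  expect_equal(h_minima_transform(prof, 0), prof)
  hm <- h_minima_transform(prof, 0.4)
  expect_equal(hm, o_hminima(prof, 0.4))
  expect_equal(max(regional_minima(hm)), 1L)   # only the deep basin survives
  # surviving minimum sits at the deep basin
  expect_true(all(which(regional_minima(hm) > 0) %in%
                  which(col(prof) %in% 20:23)))

  # a constant image is one global plateau: reconstruction lifts it by h
  # but its minima structure (one all-covering minimum) is untouched
  const <- matrix(3, 5, 5)
  hmc <- h_minima_transform(const, 2)
  expect_equal(hmc, const + 2)
  expect_identical(regional_minima(hmc), regional_minima(const))

  set.seed(9)
  img <- rand_img(20, 20, 10)
  for (h in c(0.5, 2)) {
    out <- h_minima_transform(img, h)
    expect_true(all(out >= img - 1e-12))
    expect_true(all(out - img <= h + 1e-12))
  }
  expect_error(h_minima_transform(img, -1), ">= 0")
})

test_that("extended minima equal regional minima of the h-minima transform", {
  set.seed(21)
  for (i in 1:5) {
    img <- rand_img(18, 18, 6)
    h <- runif(1, 0.5, 2)
    expect_identical(canon_labels(extended_regional_minima(img, h)),
                     canon_labels(regional_minima(h_minima_transform(img, h))))
  }
})

test_that("regional minima handle ramps, constants and offsets", {
  ramp <- matrix(rep(1:20, each = 15), 15, 20)
  rm <- regional_minima(ramp)
  expect_equal(max(rm), 1L)
  expect_true(all(which(rm > 0) %in% which(col(ramp) == 1)))

  const <- matrix(2, 8, 8)
  rmc <- regional_minima(const)
  expect_equal(max(rmc), 1L)
  expect_true(all(rmc == 1L))

  # two separated dark disks -> two components; shift invariance
  img <- matrix(200, 50, 50)
  img <- paint_disk(img, 15, 15, 5, 60)
  img <- paint_disk(img, 35, 35, 5, 60)
  expect_equal(max(extended_regional_minima(img, 30)), 2L)
  expect_identical(extended_regional_minima(img + 17, 30),
                   extended_regional_minima(img, 30))
})

test_that("skeletonization thins while preserving component structure", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(skeletonize(empty), empty)

  line <- matrix(FALSE, 10, 10)
  line[5, 2:9] <- TRUE
  expect_equal(skeletonize(line), line)

  # frame with a circular hole: skeleton stays inside the mask and keeps
  # the same number of foreground components and background holes
  mask <- matrix(TRUE, 40, 40)
  mask <- paint_disk(mask * 1, 20, 20, 8, 0) > 0
  sk <- skeletonize(mask)
  expect_true(all(mask[sk]))
  expect_equal(max(o_label(sk)), max(o_label(mask)))
  # the skeleton still encloses the hole: the hole center and the frame
  # corner lie in different components of the complement
  comp <- o_label(!sk, conn = 4)
  expect_true(comp[20, 20] != comp[1, 1] && comp[20, 20] > 0 && comp[1, 1] > 0)
  # thin: no 3x3 block fully set
  full3 <- sk[1:38, 1:38] & sk[2:39, 2:39] & sk[3:40, 3:40] &
           sk[1:38, 2:39] & sk[2:39, 1:38] & sk[3:40, 2:39] &
           sk[2:39, 3:40] & sk[1:38, 3:40] & sk[3:40, 1:38]
  expect_false(any(full3))
})
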