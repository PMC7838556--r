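test_that("structuring elements are well-formed", {
  d <- se_disk(2)
  expect_equal(dim(d$footprint), c(5, 5))
  expect_equal(d$origin, c(3L, 3L))
  expect_true(d$footprint[3, 3])
  expect_false(d$footprint[1, 1])  # corner outside the disk
  s <- se_square(3)
  expect_true(all(s$footprint))
  expect_error(structuring_element(matrix(FALSE, 2, 2)), "no TRUE cell")
  expect_error(structuring_element(matrix(TRUE, 2, 2), origin = c(5, 1)),
               "origin")
})

test_that("dilation and erosion match their definitions", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  d <- dilate(m, se_square(3))
  expect_equal(sum(d), 9)
  expect_true(all(d[3:5, 3:5]))
  # empty in, empty out
  expect_false(any(dilate(matrix(FALSE, 5, 5), se_disk(2))))
  # single pixel erodes away
  expect_false(any(erode(m, se_square(3))))
  # full mask erodes to full minus 1-px border
  f <- matrix(TRUE, 6, 6)
  e <- erode(f, se_square(3))
  expect_true(all(e[2:5, 2:5]))
  expect_equal(sum(e), 16)
})

test_that("dilate/erode equal the brute-force oracle on random cases", {
  set.seed(21)
  for (r in 1:20) {
    m <- random_mask(16, 16)
    se <- random_se()
    expect_identical(dilate(m, se), brute_dilate(m, se))
    expect_identical(erode(m, se), brute_erode(m, se))
  }
})

test_that("erosion-dilation duality holds", {
  reflect_se <- function(se) {
    f <- se$footprint[rev(seq_len(nrow(se$footprint))),
                      rev(seq_len(ncol(se$footprint))), drop = FALSE]
    structuring_element(f, origin = dim(f) + 1L - se$origin)
  }
  set.seed(22)
  for (r in 1:10) {
    # pad so border effects of the complement don't leak in
    m <- matrix(FALSE, 20, 20)
    m[5:16, 5:16] <- random_mask(12, 12)
    se <- random_se()
    lhs <- erode(m, se)[5:16, 5:16]
    rhs <- !dilate(!m, reflect_se(se))
    expect_identical(lhs, rhs[5:16, 5:16])
  }
})

test_that("closing is extensive, idempotent and fills small holes", {
  # a closed set stays fixed
  solid <- matrix(FALSE, 60, 60); solid[6:55, 6:55] <- TRUE
  expect_identical(close_tumor_region(solid, se_disk(5)), solid)
  # hole narrower than the SE is filled
  holed <- solid; holed[30:49, 30:49] <- FALSE  # 20x20 hole
  closed <- close_tumor_region(holed, se_disk(15))
  expect_identical(closed, solid)
  # extensivity and idempotence on random masks
  set.seed(23)
  for (r in 1:15) {
    m <- random_mask(24, 24, 0.3)
    se <- random_se()
    c1 <- close_tumor_region(m, se)
    expect_true(all(c1[m]))              # result contains the input
    expect_identical(close_tumor_region(c1, se), c1)  # idempotent
  }
})

test_that("PTS score equals the analytic ground truth on fixtures", {
  # stroma only outside the tumor: score 0
  w0 <- make_wsi_labelmap(wsi_geometry_spec(c(120, 120), c(11, 11, 100, 100)))
  r0 <- compute_pts(w0$labels, se_disk(10))
  expect_equal(r0$score, 0)
  expect_equal(r0$tumor_area, 10000)

  # the canonical 100x100 tumor with central 20x20 stroma hole
  w1 <- make_wsi_labelmap(wsi_geometry_spec(c(140, 140), c(21, 21, 100, 100),
                                            holes = list(c(61, 61, 20, 20))))
  for (se in list(se_disk(15), se_disk(20), se_square(31))) {
    r1 <- compute_pts(w1$labels, se)
    expect_identical(r1$tumor_area, 9600L)
    expect_identical(r1$pts_area, 400L)
    expect_equal(r1$score, 400 / 9600)
  }

  # degenerate: no tumor anywhere
  stroma_only <- matrix(TISSUE_CLASSES[["STROMA"]], 30, 30)
  expect_error(compute_pts(stroma_only, se_disk(3)), "no tumor in slide")
})

test_that("PTS area never decreases when the SE grows", {
  set.seed(24)
  for (r in 1:5) {
    labels <- matrix(sample(c(1L, 2L, 7L), 900, TRUE, prob = c(0.4, 0.3, 0.3)),
                     30, 30)
    areas <- vapply(c(1, 2, 4, 6), function(rad)
      compute_pts(labels, se_disk(rad))$pts_area, numeric(1))
    expect_true(all(diff(areas) >= 0))
  }
})

test_that("PTS result is invariant under translation of the label map", {
  w <- make_wsi_labelmap(wsi_geometry_spec(c(160, 160), c(31, 31, 80, 80),
                                           holes = list(c(61, 61, 14, 14))))
  r1 <- compute_pts(w$labels, se_disk(8))
  shifted <- matrix(TISSUE_CLASSES[["NORMAL"]], 160, 160)
  shifted[11:160, 6:160] <- w$labels[1:150, 1:155]
  r2 <- compute_pts(shifted, se_disk(8))
  expect_equal(r1$tumor_area, r2$tumor_area)
  expect_equal(r1$pts_area, r2$pts_area)
  expect_equal(r1$score, r2$score)
})

test_that("small-object filtering removes salt noise before closing", {
  labels <- matrix(TISSUE_CLASSES[["NORMAL"]], 40, 40)
  labels[10:30, 10:30] <- TISSUE_CLASSES[["TUMOR"]]
  labels[2, 2] <- TISSUE_CLASSES[["TUMOR"]]       # isolated speck
  labels[15:20, 15:20] <- TISSUE_CLASSES[["STROMA"]]
  r_raw <- compute_pts(labels, se_disk(4))
  r_filt <- compute_pts(labels, se_disk(4), min_object_size = 5L)
  expect_equal(r_raw$tumor_area, r_filt$tumor_area + 1)
  expect_equal(r_filt$pts_area, 36L)
})
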