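# First-order and 2D shape feature extraction.

test_that("skewness and kurtosis follow the population central-moment definitions", {
  expect_equal(first_order_features(c(1, 2, 3))$skewness, 0)
  # m2 = 1, m4 = 1 -> non-excess kurtosis exactly 1
  expect_equal(first_order_features(c(-1, -1, 1, 1))$kurtosis, 1.0)
  # a normal sample has kurtosis ~ 3 (non-excess convention)
  set.seed(101)
  x <- rnorm(1e5)
  expect_equal(first_order_features(x)$kurtosis, 3, tolerance = 0.05)
  expect_error(first_order_features(rep(2, 10)),
               class = "radformal_degenerate_input")
  expect_error(first_order_features(1), class = "radformal_degenerate_input")
})

test_that("skewness and kurtosis are invariant under positive affine intensity maps", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.5, 4))
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    f1 <- first_order_features(x)
    f2 <- first_order_features(a * x + b)
    expect_equal(f2$skewness, f1$skewness, tolerance = 1e-10)
    expect_equal(f2$kurtosis, f1$kurtosis, tolerance = 1e-10)
  }
})

test_that("a single pixel yields the marching-squares diamond", {
  sh <- shape2d_features(slice_mask(matrix(1, 1, 1), c(0.6, 0.6)))
  expect_equal(sh$mesh_surface, 0.6 * 0.6 / 2)
  expect_equal(sh$elongation, 1)
})

test_that("rasterized disks approach a circle: area within 5%, sphericity and elongation near 1", {
  for (r in c(10L, 25L)) {
    sh <- shape2d_features(disk_mask(r))
    expect_equal(sh$mesh_surface, pi * (r * 0.6)^2,
                 tolerance = 0.05)
    expect_gt(sh$sphericity, 0.95)
    expect_lte(sh$sphericity, 1.05)
    expect_gt(sh$elongation, 0.95)
  }
})

test_that("a thin bar is elongated and non-spherical", {
  # covariance oracle by direct arithmetic on pixel coordinates
  mk <- matrix(1L, 1, 20)
  sh <- shape2d_features(slice_mask(mk, c(0.6, 0.6)))
  coords <- (0:19) * 0.6
  expect_lt(sh$elongation, 0.3)
  expect_lt(sh$sphericity, 1)
  # one-pixel-wide: minor eigenvalue is exactly zero
  expect_equal(sh$elongation, 0)
})

test_that("sphericity stays below 1 + tolerance and elongation in [0,1] on random blobs", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    mk <- matrix(as.integer(runif(n * n) < 0.45), n, n)
    if (sum(mk) == 0L) mk[sample(n * n, 1)] <- 1L
    sh <- shape2d_features(slice_mask(mk, c(0.6, 0.6)))
    expect_lte(sh$sphericity, 1.05)
    expect_gte(sh$elongation, 0)
    expect_lte(sh$elongation, 1)
    expect_gt(sh$mesh_surface, 0)
  }
})

test_that("z-score normalization and sigma clipping behave as defined", {
  set.seed(3)
  px <- matrix(rnorm(100, 50, 5), 10, 10)
  img <- slice_image(px, c(0.6, 0.6))
  msk <- slice_mask(matrix(1L, 10, 10), c(0.6, 0.6))
  out <- preprocess_slice(img, msk, preprocess_config())
  expect_true(all(out$image$pixels <= 3 & out$image$pixels >= -3))

  # an outlier at mean + 10 sd is clipped to exactly +3
  px2 <- px; px2[5, 5] <- mean(px) + 10 * sd(px)
  out2 <- preprocess_slice(slice_image(px2, c(0.6, 0.6)), msk,
                           preprocess_config())
  expect_equal(max(out2$image$pixels), 3)

  # no normalization + already at target spacing -> identity
  out3 <- preprocess_slice(img, msk, preprocess_config(normalize = FALSE))
  expect_identical(out3$image$pixels, px)
  expect_identical(out3$mask$pixels, msk$pixels)

  expect_error(preprocess_slice(slice_image(matrix(5, 4, 4), c(0.6, 0.6)),
                                slice_mask(matrix(1L, 4, 4), c(0.6, 0.6)),
                                preprocess_config()),
               class = "radformal_degenerate_input")
})

test_that("resampling changes the grid to the target spacing and preserves the mask", {
  set.seed(4)
  img <- slice_image(matrix(rnorm(30 * 30), 30, 30), c(1.2, 1.2))
  mkpx <- matrix(0L, 30, 30); mkpx[10:20, 12:22] <- 1L
  msk <- slice_mask(mkpx, c(1.2, 1.2))
  out <- preprocess_slice(img, msk, preprocess_config(normalize = FALSE))
  expect_equal(out$image$spacing, c(0.6, 0.6))
  expect_equal(dim(out$image$pixels), dim(out$mask$pixels))
  expect_true(all(out$mask$pixels %in% c(0L, 1L)))
  # the rectangle roughly doubles its pixel count per axis
  expect_gt(sum(out$mask$pixels), 3 * sum(mkpx))
})

test_that("cohort extraction skips empty masks, is deterministic, and names failing patients", {
  set.seed(5)
  mk_slice <- function(k, empty = FALSE) {
    px <- matrix(rnorm(400, 100, 10), 20, 20)
    mk <- matrix(0L, 20, 20)
    if (!empty) mk[6:15, 6:15] <- 1L
    list(image = slice_image(px, c(0.6, 0.6), k),
         mask = slice_mask(mk, c(0.6, 0.6)))
  }
  pat <- list(patient_id = "p1",
              slices = list(mk_slice(1), mk_slice(2, empty = TRUE),
                            mk_slice(3)))
  tab <- extract_cohort_features(list(pat))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$slice_index, c(1L, 3L))
  expect_identical(extract_cohort_features(list(pat)), tab)

  bad <- list(patient_id = "px",
              slices = list(mk_slice(1, empty = TRUE)))
  expect_error(extract_cohort_features(list(bad)), "px",
               class = "radformal_empty_mask")
})

test_that("disk-lesion patients have uniformly high sphericity", {
  set.seed(6)
  slices <- lapply(1:3, function(k) {
    mk <- disk_mask(12L)
    px <- matrix(rnorm(length(mk$pixels), 100, 15), nrow(mk$pixels))
    list(image = slice_image(px, c(0.6, 0.6), k), mask = mk)
  })
  tab <- extract_cohort_features(list(list(patient_id = "d1",
                                           slices = slices)))
  expect_true(all(tab$sphericity > 0.9))
})
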