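#' Construct a 2D image slice
#'
#' A slice holds a numeric pixel matrix together with its physical in-plane
#' pixel spacing in millimetres and its position in the exam stack.
#'
#' @param pixels Numeric matrix of intensities (arbitrary units).
#' @param spacing Numeric length-2 vector, physical (row, col) pixel size in
#'   mm; both components must be positive.
#' @param slice_index Integer position of the slice in the stack.
#' @return An object of class `radformal_slice`.
#' @export
slice_image <- function(pixels, spacing, slice_index = 1L) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L)
    .rf_stop("bad_input", "slice pixel grid is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    .rf_stop("bad_input", "spacing must be two positive numbers (mm)")
  structure(list(pixels = pixels, spacing = spacing,
                 slice_index = as.integer(slice_index)),
            class = "radformal_slice")
}

#' Construct a binary segmentation mask aligned to a slice
#'
#' @param pixels Matrix with values in \{0, 1\} (anything > 0.5 is foreground).
#' @param spacing Physical (row, col) pixel size in mm, matching the image.
#' @return An object of class `radformal_mask`.
#' @export
slice_mask <- function(pixels, spacing) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L)
    .rf_stop("bad_input", "mask pixel grid is empty")
  storage.mode(pixels) <- "integer"
  pixels[] <- as.integer(pixels > 0L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    .rf_stop("bad_input", "spacing must be two positive numbers (mm)")
  structure(list(pixels = pixels, spacing = spacing),
            class = "radformal_mask")
}

#' Preprocessing settings for feature extraction
#'
#' Defaults mirror a standard radiomics configuration for fluid-sensitive
#' MRI: z-score intensity normalization with outliers clipped at 3 standard
#' deviations, in-plane resampling to 0.6 x 0.6 mm with cubic-spline
#' interpolation (nearest neighbour for the mask), and strictly 2D feature
#' computation. `bin_count` is the fixed-bin-count setting used by gray-level
#' texture features; none of the features computed here depend on it, so it
#' is retained only for provenance in run manifests.
#'
#' @param normalize Logical; z-score the slice intensities.
#' @param remove_outliers_sigma Positive number; clip normalized intensities
#'   to +/- this many standard deviations.
#' @param resample_spacing Target in-plane (row, col) spacing in mm.
#' @param bin_count Integer, inert provenance setting (see above).
#' @param force_2d Logical; always `TRUE` (features are per-slice).
#' @return An object of class `radformal_config`.
#' @export
preprocess_config <- function(normalize = TRUE, remove_outliers_sigma = 3,
                              resample_spacing = c(0.6, 0.6), bin_count = 50L,
                              force_2d = TRUE) {
  if (!is.numeric(remove_outliers_sigma) || remove_outliers_sigma <= 0)
    .rf_stop("bad_input", "remove_outliers_sigma must be > 0")
  resample_spacing <- as.numeric(resample_spacing)
  if (length(resample_spacing) != 2L || any(resample_spacing <= 0))
    .rf_stop("bad_input", "resample_spacing must be two positive numbers")
  structure(list(normalize = isTRUE(normalize),
                 remove_outliers_sigma = remove_outliers_sigma,
                 resample_spacing = resample_spacing,
                 bin_count = as.integer(bin_count),
                 force_2d = TRUE),
            class = "radformal_config")
}

# Separable interpolation of a matrix onto a new in-plane grid.  Old pixel
# centres sit at (i-1)*spacing; new centres at (j-1)*target, covering the
# same physical extent (no extrapolation).  Interpolating natural cubic
# splines row-wise then column-wise; this is an order-3 spline resampler,
# not a reproduction of any particular library's B-spline.
.rf_resample_grid <- function(n_old, sp_old, sp_new) {
  extent <- (n_old - 1L) * sp_old
  seq(0, extent, by = sp_new)
}

.rf_resample_spline <- function(mat, spacing, target) {
  xo <- (seq_len(nrow(mat)) - 1) * spacing[1]
  yo <- (seq_len(ncol(mat)) - 1) * spacing[2]
  xn <- .rf_resample_grid(nrow(mat), spacing[1], target[1])
  yn <- .rf_resample_grid(ncol(mat), spacing[2], target[2])
  interp1 <- function(x, y, xout) {
    if (length(x) == 1L) return(rep(y, length(xout)))
    if (length(x) == 2L) return(stats::approx(x, y, xout)$y)
    stats::splinefun(x, y, method = "natural")(xout)
  }
  tmp <- matrix(0, nrow(mat), length(yn))
  for (i in seq_len(nrow(mat))) tmp[i, ] <- interp1(yo, mat[i, ], yn)
  out <- matrix(0, length(xn), length(yn))
  for (j in seq_len(ncol(tmp))) out[, j] <- interp1(xo, tmp[, j], xn)
  out
}

.rf_resample_nn <- function(mat, spacing, target) {
  xn <- .rf_resample_grid(nrow(mat), spacing[1], target[1])
  yn <- .rf_resample_grid(ncol(mat), spacing[2], target[2])
  ri <- pmin(pmax(round(xn / spacing[1]) + 1L, 1L), nrow(mat))
  ci <- pmin(pmax(round(yn / spacing[2]) + 1L, 1L), ncol(mat))
  mat[ri, ci, drop = FALSE]
}

#' Preprocess one slice/mask pair
#'
#' Applies, in order: z-score normalization of the whole slice (if enabled),
#' clipping of normalized values at `+/- remove_outliers_sigma`, and in-plane
#' resampling to `resample_spacing` (cubic spline for the image, nearest
#' neighbour for the mask, which is then re-binarized). When the slice is
#' already at the target spacing no resampling is performed.
#'
#' @param image A [slice_image()].
#' @param mask A [slice_mask()] aligned to `image`.
#' @param config A [preprocess_config()].
#' @return List with elements `image` and `mask`, preprocessed.
#' @export
preprocess_slice <- function(image, mask, config = preprocess_config()) {
  stopifnot(inherits(image, "radformal_slice"), inherits(mask, "radformal_mask"))
  if (!identical(dim(image$pixels), dim(mask$pixels)) ||
      !isTRUE(all.equal(image$spacing, mask$spacing)))
    .rf_stop("bad_input", "mask is not aligned to its image")
  px <- image$pixels
  if (config$normalize) {
    mu <- mean(px)
    sdv <- stats::sd(as.vector(px))
    if (!is.finite(sdv) || sdv == 0)
      .rf_stop("degenerate_input",
               "cannot normalize a slice with zero intensity variance")
    px <- (px - mu) / sdv
    s <- config$remove_outliers_sigma
    px[px > s] <- s
    px[px < -s] <- -s
  }
  sp <- image$spacing
  tg <- config$resample_spacing
  mk <- mask$pixels
  if (!isTRUE(all.equal(sp, tg))) {
    px <- .rf_resample_spline(px, sp, tg)
    mk <- .rf_resample_nn(mk, sp, tg)
    mk[] <- as.integer(mk > 0L)
    sp <- tg
  }
  if (sum(mk) == 0L)
    .rf_stop("empty_mask", "mask is empty after resampling")
  list(image = slice_image(px, sp, image$slice_index),
       mask = slice_mask(mk, sp))
}

#' First-order intensity features: skewness and kurtosis
#'
#' Central-moment definitions with population (1/n) denominators:
#' skewness = m3 / m2^1.5 and kurtosis = m4 / m2^2, where mk is the k-th
#' central sample moment. Kurtosis is non-excess, so a normal distribution
#' has kurtosis 3.
#'
#' @param values Numeric vector of masked intensities (>= 2 values with
#'   nonzero variance).
#' @return Named list with `skewness` and `kurtosis`.
#' @export
first_order_features <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    .rf_stop("degenerate_input", "need at least 2 intensity values")
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  if (m2 == 0)
    .rf_stop("degenerate_input", "zero intensity variance inside the mask")
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  list(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# Marching squares on a binary mask in physical coordinates.  The mask is
# zero-padded, every 2x2 pixel neighbourhood is classified by its corner
# pattern, and the iso-0.5 contour crosses cell edges at their midpoints.
# Area and contour length follow from fixed per-pattern contributions;
# saddle patterns are resolved as two separate corner cuts.
.rf_marching_squares <- function(mask, spacing) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  R <- nrow(m); C <- ncol(m)
  tl <- m[-R, -C]; tr <- m[-R, -1L]
  bl <- m[-1L, -C]; br <- m[-1L, -1L]
  code <- tl + 2L * tr + 4L * bl + 8L * br
  cnt <- tabulate(as.vector(code) + 1L, nbins = 16L)
  dr <- spacing[1]; dc <- spacing[2]
  cell <- dr * dc
  corner <- sqrt((dr / 2)^2 + (dc / 2)^2)
  nset <- c(0, 1, 1, 2, 1, 2, 2, 3, 1, 2, 2, 3, 2, 3, 3, 4)
  afrac <- numeric(16L); plen <- numeric(16L)
  for (k in 0:15) {
    n <- nset[k + 1L]
    if (n == 1) { afrac[k + 1L] <- 1 / 8; plen[k + 1L] <- corner }
    else if (n == 3) { afrac[k + 1L] <- 7 / 8; plen[k + 1L] <- corner }
    else if (n == 4) { afrac[k + 1L] <- 1 }
    else if (n == 2) {
      if (k %in% c(3L, 12L)) { afrac[k + 1L] <- 1 / 2; plen[k + 1L] <- dc }
      else if (k %in% c(5L, 10L)) { afrac[k + 1L] <- 1 / 2; plen[k + 1L] <- dr }
      else { afrac[k + 1L] <- 1 / 4; plen[k + 1L] <- 2 * corner }
    }
  }
  list(area = sum(cnt * afrac) * cell, contour_length = sum(cnt * plen))
}

# Multiplicative bias correction for the digital contour length (Kulpa's
# constant pi*(1+sqrt(2))/8).  The raw marching-squares polygon overstates
# the length of smooth isotropically-oriented boundaries by exactly the
# reciprocal of this factor, so the corrected estimator is consistent:
# perimeters (and hence sphericity) of rasterized smooth shapes converge to
# their analytic values as resolution increases.
.rf_perimeter_correction <- pi * (1 + sqrt(2)) / 8

#' 2D shape features of a binary mask
#'
#' The lesion contour is traced by marching squares in physical coordinates.
#' `mesh_surface` is the enclosed area (mm^2) and `perimeter` the
#' bias-corrected contour length (mm); `sphericity = 2*sqrt(pi*A)/P`
#' measures roundness relative to a circle. `elongation` is
#' `sqrt(lambda_minor/lambda_major)` from the eigenvalues of the covariance
#' of mask pixel-centre physical coordinates, so 1 is isotropic and values
#' near 0 are line-like. Disconnected masks are treated as a union: areas
#' and contour lengths are summed and the covariance is taken over all
#' foreground pixels.
#'
#' @param mask A [slice_mask()] with at least one foreground pixel.
#' @return Named list: `mesh_surface`, `perimeter`, `sphericity`,
#'   `elongation`.
#' @export
shape2d_features <- function(mask) {
  stopifnot(inherits(mask, "radformal_mask"))
  mk <- mask$pixels
  if (sum(mk) == 0L)
    .rf_stop("empty_mask", "cannot compute shape features of an empty mask")
  ms <- .rf_marching_squares(mk, mask$spacing)
  perim <- ms$contour_length * .rf_perimeter_correction
  sph <- 2 * sqrt(pi * ms$area) / perim
  idx <- which(mk == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 1L) {
    elong <- 1  # single pixel: isotropic point by convention
  } else {
    xy <- cbind(idx[, 1] * mask$spacing[1], idx[, 2] * mask$spacing[2])
    xy <- sweep(xy, 2, colMeans(xy))
    cov <- crossprod(xy) / n  # population covariance
    ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    elong <- if (ev[1] == 0) 1 else sqrt(ev[2] / ev[1])
  }
  list(mesh_surface = ms$area, perimeter = perim, sphericity = sph,
       elongation = elong)
}

#' Extract the five selected features for a cohort of slice stacks
#'
#' Runs [preprocess_slice()] and computes skewness, kurtosis (first-order,
#' inside the mask) and elongation, sphericity, mesh surface (2D shape) for
#' every slice with a non-empty mask. Slices with empty masks are skipped;
#' a patient with no usable slice is an error.
#'
#' @param stacks A list of patients; each patient is a list with
#'   `patient_id` and `slices`, itself a list of `list(image, mask)` pairs
#'   ([slice_image()] / [slice_mask()]).
#' @param config A [preprocess_config()].
#' @return A feature table: `data.frame` with columns `patient_id`,
#'   `slice_index`, `kurtosis`, `skewness`, `elongation`, `sphericity`,
#'   `mesh_surface`, ordered by ascending `slice_index` within patient.
#' @export
extract_cohort_features <- function(stacks, config = preprocess_config()) {
  rows <- list()
  for (pat in stacks) {
    pid <- pat$patient_id
    prow <- list()
    for (sl in pat$slices) {
      if (sum(sl$mask$pixels) == 0L) next
      pp <- tryCatch(preprocess_slice(sl$image, sl$mask, config),
                     radformal_empty_mask = function(e) NULL)
      if (is.null(pp)) next
      fo <- first_order_features(pp$image$pixels[pp$mask$pixels == 1L])
      sh <- shape2d_features(pp$mask)
      prow[[length(prow) + 1L]] <- data.frame(
        patient_id = pid, slice_index = pp$image$slice_index,
        kurtosis = fo$kurtosis, skewness = fo$skewness,
        elongation = sh$elongation, sphericity = sh$sphericity,
        mesh_surface = sh$mesh_surface, stringsAsFactors = FALSE)
    }
    if (length(prow) == 0L)
      .rf_stop("empty_mask", "patient '%s' has no slice with a non-empty mask",
               pid)
    df <- do.call(rbind, prow)
    rows[[length(rows) + 1L]] <- df[order(df$slice_index), , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
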