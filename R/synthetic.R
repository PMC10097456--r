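# Synthetic labelled cohorts.  Sequence mode draws discretized per-slice
# level patterns directly and controls, per group, the probability that a
# patient's action chain satisfies the disease property; image mode draws
# elliptical lesions with controllable shape and intensity-distribution
# knobs and exercises the extraction stage end-to-end.

#' Specification of a synthetic cohort
#'
#' Defaults are a 47-patient cohort: 21 group-A and 26 group-B patients,
#' 5--20 slices per exam (a plausible range for extremity MRI), and
#' per-group property-satisfaction rates of 21/26 for group B and 7/21 for
#' group A.
#'
#' @param n_group_a,n_group_b Patient counts per group.
#' @param slices_range Inclusive range of slices per patient.
#' @param mode `"sequence"` (discretized action chains) or `"image"`
#'   (elliptical lesion stacks).
#' @param p_pattern_a,p_pattern_b Probability that a patient of the group
#'   carries the disease pattern.
#' @param fixed_counts Logical; when `TRUE` the number of satisfiers per
#'   group is exactly `round(p * n)` instead of Bernoulli-sampled.
#' @param seed Integer seed; cohorts are reproducible bit-for-bit from
#'   (spec, seed).
#' @param frame_dim,frame_spacing Image-mode frame size (pixels) and pixel
#'   spacing (mm).
#' @param area_range Lesion area range (mm^2), image mode.
#' @param axis_ratio_range Minor/major axis ratio range, image mode.
#' @param intensity_shape_range Gamma shape-parameter range controlling the
#'   skewness/kurtosis of lesion intensities, image mode.
#' @param intensity_location,intensity_scale Location offset and gamma
#'   scale of lesion intensities (arbitrary units), image mode.
#' @param background_sd Standard deviation of the Gaussian background.
#' @return Object of class `radformal_cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 21L, n_group_b = 26L,
                        slices_range = c(5L, 20L),
                        mode = c("sequence", "image"),
                        p_pattern_a = 7 / 21, p_pattern_b = 21 / 26,
                        fixed_counts = FALSE, seed = 1L,
                        frame_dim = c(64L, 64L), frame_spacing = c(0.8, 0.8),
                        area_range = c(60, 400),
                        axis_ratio_range = c(0.4, 1),
                        intensity_shape_range = c(2, 10),
                        intensity_location = 100, intensity_scale = 20,
                        background_sd = 5) {
  mode <- match.arg(mode)
  stopifnot(n_group_a >= 0, n_group_b >= 0,
            p_pattern_a >= 0, p_pattern_a <= 1,
            p_pattern_b >= 0, p_pattern_b <= 1,
            slices_range[1] >= 1, slices_range[2] >= slices_range[1])
  max_area <- prod((frame_dim - 8L) * frame_spacing)
  if (mode == "image" && area_range[2] > max_area)
    .rf_stop("bad_input", "requested lesion area does not fit the frame")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 slices_range = as.integer(slices_range), mode = mode,
                 p_pattern_a = p_pattern_a, p_pattern_b = p_pattern_b,
                 fixed_counts = isTRUE(fixed_counts), seed = as.integer(seed),
                 frame_dim = as.integer(frame_dim),
                 frame_spacing = frame_spacing, area_range = area_range,
                 axis_ratio_range = axis_ratio_range,
                 intensity_shape_range = intensity_shape_range,
                 intensity_location = intensity_location,
                 intensity_scale = intensity_scale,
                 background_sd = background_sd),
            class = "radformal_cohort_spec")
}

.rf_uniform_levels <- function(n_slices) {
  matrix(sample(1:3, 5L * n_slices, replace = TRUE), nrow = 5L)
}

# Implant the disease pattern: four consecutive slices with sphericity at
# level 3 immediately followed by kurtosis at level 1.  Consecutive slices
# guarantee the restricted recursion of the last two pattern steps is
# respected, because the actions between consecutive pairs are skewness /
# elongation / meshsurface actions, which the exclusion set never names.
.rf_implant_pattern <- function(levels) {
  n <- ncol(levels)
  start <- if (n == 4L) 1L else sample.int(n - 3L, 1L)
  levels[1L, start:(start + 3L)] <- 3L  # sphericity row
  levels[2L, start:(start + 3L)] <- 1L  # kurtosis row
  levels
}

.rf_draw_patient_levels <- function(n_slices, satisfier, props, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    lev <- .rf_uniform_levels(n_slices)
    if (satisfier) lev <- .rf_implant_pattern(lev)
    seqc <- action_sequence_from_levels("tmp", lev)
    ok <- check_patient(chain_lts(seqc$actions, seqc$slice_ids), props)$verdict
    if (ok == satisfier) return(lev)
  }
  .rf_stop("bad_input",
           "could not draw a %s sequence in %d attempts",
           if (satisfier) "satisfying" else "non-satisfying", max_tries)
}

#' Generate a sequence-mode synthetic cohort
#'
#' Each patient receives a per-slice level matrix with all levels uniform
#' on \{1,2,3\}; patients drawn as pattern carriers get the disease pattern
#' implanted (four consecutive high-sphericity / low-kurtosis slices),
#' while non-carriers are redrawn (rejection sampling against the model
#' checker) until their chain does not satisfy the property. Every
#' patient's ground-truth flag therefore agrees with the checker's verdict
#' by construction.
#'
#' @param spec A [cohort_spec()] with `mode = "sequence"`.
#' @param props Property set to control satisfaction against (default
#'   [sts_property_set()]).
#' @return Object of class `radformal_cohort`: list of patients with
#'   `patient_id`, `group`, `satisfier` and `sequence`
#'   (`radformal_actionseq`), plus the generating `spec`.
#' @export
generate_action_cohort <- function(spec, props = sts_property_set()) {
  stopifnot(inherits(spec, "radformal_cohort_spec"))
  if (spec$mode != "sequence")
    .rf_stop("bad_input", "spec mode must be 'sequence'")
  set.seed(spec$seed)
  groups <- c(rep("A", spec$n_group_a), rep("B", spec$n_group_b))
  ids <- sprintf("%s%03d", groups,
                 c(seq_len(spec$n_group_a), seq_len(spec$n_group_b)))
  flags <- logical(length(groups))
  for (g in c("A", "B")) {
    idx <- which(groups == g)
    p <- if (g == "A") spec$p_pattern_a else spec$p_pattern_b
    if (spec$fixed_counts) {
      k <- round(p * length(idx))
      flags[sample(idx, k)] <- TRUE
    } else {
      flags[idx] <- stats::runif(length(idx)) < p
    }
  }
  patients <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    n_slices <- sample(seq(spec$slices_range[1], spec$slices_range[2]), 1L)
    if (flags[i]) n_slices <- max(n_slices, 4L)  # pattern needs 4 slices
    lev <- .rf_draw_patient_levels(n_slices, flags[i], props)
    patients[[i]] <- list(patient_id = ids[i], group = groups[i],
                          satisfier = flags[i],
                          sequence = action_sequence_from_levels(ids[i], lev))
  }
  structure(list(patients = patients, spec = spec, mode = "sequence"),
            class = "radformal_cohort")
}

.rf_ellipse_mask <- function(frame_dim, spacing, area, ratio, angle, center) {
  a <- sqrt(area / (pi * ratio))  # semi-major (mm)
  b <- a * ratio
  r <- (seq_len(frame_dim[1]) - center[1]) * spacing[1]
  c_ <- (seq_len(frame_dim[2]) - center[2]) * spacing[2]
  X <- outer(r, rep(1, frame_dim[2]))
  Y <- outer(rep(1, frame_dim[1]), c_)
  U <- X * cos(angle) + Y * sin(angle)
  V <- -X * sin(angle) + Y * cos(angle)
  matrix(as.integer((U / a)^2 + (V / b)^2 <= 1), frame_dim[1], frame_dim[2])
}

#' Generate an image-mode synthetic cohort
#'
#' Per slice, an elliptical lesion with controlled area (driving mesh
#' surface), axis ratio (driving elongation and sphericity) and a
#' gamma-distributed intensity texture (whose shape parameter drives
#' skewness and kurtosis) is placed on a Gaussian background. Image mode
#' exercises extraction and the downstream stages through known monotone
#' relationships; it does not attempt to realize a prescribed discretized
#' pattern through images.
#'
#' @param spec A [cohort_spec()] with `mode = "image"`.
#' @return A `radformal_cohort` whose patients carry `stacks` (slice
#'   image/mask pairs); `satisfier` flags are `NA` in image mode.
#' @export
generate_image_cohort <- function(spec) {
  stopifnot(inherits(spec, "radformal_cohort_spec"))
  if (spec$mode != "image")
    .rf_stop("bad_input", "spec mode must be 'image'")
  set.seed(spec$seed)
  groups <- c(rep("A", spec$n_group_a), rep("B", spec$n_group_b))
  ids <- sprintf("%s%03d", groups,
                 c(seq_len(spec$n_group_a), seq_len(spec$n_group_b)))
  patients <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    n_slices <- sample(seq(spec$slices_range[1], spec$slices_range[2]), 1L)
    slices <- vector("list", n_slices)
    for (k in seq_len(n_slices)) {
      area <- stats::runif(1, spec$area_range[1], spec$area_range[2])
      ratio <- stats::runif(1, spec$axis_ratio_range[1],
                            spec$axis_ratio_range[2])
      angle <- stats::runif(1, 0, pi)
      center <- spec$frame_dim / 2 + stats::runif(2, -2, 2)
      mk <- .rf_ellipse_mask(spec$frame_dim, spec$frame_spacing, area, ratio,
                             angle, center)
      shape <- stats::runif(1, spec$intensity_shape_range[1],
                            spec$intensity_shape_range[2])
      px <- matrix(stats::rnorm(prod(spec$frame_dim), 0, spec$background_sd),
                   spec$frame_dim[1], spec$frame_dim[2])
      nin <- sum(mk)
      px[mk == 1L] <- spec$intensity_location +
        stats::rgamma(nin, shape = shape, scale = spec$intensity_scale)
      slices[[k]] <- list(image = slice_image(px, spec$frame_spacing, k),
                          mask = slice_mask(mk, spec$frame_spacing))
    }
    patients[[i]] <- list(patient_id = ids[i], group = groups[i],
                          satisfier = NA,
                          stacks = list(patient_id = ids[i], slices = slices))
  }
  structure(list(patients = patients, spec = spec, mode = "image"),
            class = "radformal_cohort")
}

#' Run the full pipeline on a synthetic cohort and score it
#'
#' Image-mode cohorts go through feature extraction and discretization;
#' sequence-mode cohorts are already discretized. Every patient's chain is
#' model-checked against `props`, a true verdict predicts group B, and the
#' predictions are scored against the ground-truth groups.
#'
#' @param cohort A `radformal_cohort`.
#' @param props Property set (default [sts_property_set()]).
#' @param config Preprocessing settings for image mode.
#' @return List with `metrics` ([classification_metrics()] report), `cui`
#'   ([clinical_utility()]), `confusion` and a per-patient `verdicts`
#'   data.frame.
#' @export
evaluate_end_to_end <- function(cohort, props = sts_property_set(),
                                config = preprocess_config()) {
  stopifnot(inherits(cohort, "radformal_cohort"))
  sequences <- cohort_sequences(cohort, props = props, config = config)
  verdicts <- vapply(sequences, function(s)
    check_patient(chain_lts(s$actions, s$slice_ids), props)$verdict,
    logical(1))
  truth <- stats::setNames(
    vapply(cohort$patients, `[[`, character(1), "group"),
    vapply(cohort$patients, `[[`, character(1), "patient_id"))
  predicted <- stats::setNames(ifelse(verdicts, "B", "A"), names(sequences))
  cm <- confusion_matrix(truth, predicted)
  metrics <- classification_metrics(cm)
  list(metrics = metrics, cui = clinical_utility(metrics), confusion = cm,
       verdicts = data.frame(patient_id = names(sequences),
                             group = truth[names(sequences)],
                             verdict = verdicts,
                             predicted = predicted[names(sequences)],
                             row.names = NULL))
}

#' Action sequences of a cohort (extracting and discretizing if needed)
#'
#' @param cohort A `radformal_cohort`.
#' @param props Unused for sequence mode; kept for signature symmetry.
#' @param config Preprocessing settings for image mode.
#' @return Named list of `radformal_actionseq`.
#' @export
cohort_sequences <- function(cohort, props = NULL,
                             config = preprocess_config()) {
  if (cohort$mode == "sequence") {
    seqs <- lapply(cohort$patients, `[[`, "sequence")
  } else {
    table <- extract_cohort_features(lapply(cohort$patients, `[[`, "stacks"),
                                     config)
    scheme <- fit_bins(table)
    lev <- assign_levels(table, scheme)
    seqs <- lapply(cohort$patients, function(p)
      to_action_sequence(lev[lev$patient_id == p$patient_id, , drop = FALSE]))
  }
  stats::setNames(seqs, vapply(cohort$patients, `[[`, character(1),
                               "patient_id"))
}
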