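# End-to-end orchestration: features -> levels -> CCS models -> verdicts
# -> metrics, with every intermediate persisted in a re-readable format and
# a machine-readable run manifest.

#' Configuration of a pipeline run
#'
#' Exactly one input modality must be given: a per-slice feature CSV
#' (`feature_csv`) or a directory of NIfTI image/mask pairs (`image_dir`,
#' see [read_nifti_cohort()]).
#'
#' @param feature_csv Path to a feature table CSV, or `NULL`.
#' @param image_dir Cohort directory with `images/` and `masks/`, or `NULL`.
#' @param labels_csv Path to the `patient_id,group` label CSV (optional;
#'   without labels only verdicts are produced, no metrics).
#' @param property_file Path to a property file; `NULL` uses the bundled
#'   disease property set.
#' @param scheme_file Path to a stored binning scheme JSON to apply instead
#'   of fitting one on this cohort, or `NULL` to fit.
#' @param out_dir Output directory (created if missing).
#' @param config A [preprocess_config()].
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @param verbose Logical; log per-stage progress to stderr.
#' @return Object of class `radformal_run_config`.
#' @export
run_config <- function(feature_csv = NULL, image_dir = NULL,
                       labels_csv = NULL, property_file = NULL,
                       scheme_file = NULL, out_dir = "radformal_out",
                       config = preprocess_config(), seed = 1L,
                       verbose = FALSE) {
  n_inputs <- sum(!is.null(feature_csv), !is.null(image_dir))
  if (n_inputs != 1L)
    .rf_stop("bad_input",
             "exactly one input modality (feature_csv or image_dir) is required")
  structure(list(feature_csv = feature_csv, image_dir = image_dir,
                 labels_csv = labels_csv, property_file = property_file,
                 scheme_file = scheme_file, out_dir = out_dir,
                 config = config, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "radformal_run_config")
}

.rf_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[radformal] ", fmt), ...))
}

# Polynomial rolling hash (mod 2^31-1) of the deparsed configuration, for
# the manifest.
.rf_config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline and persist every stage
#'
#' Writes, under `out_dir`: `features.csv`, `levels.csv`,
#' `binning_scheme.json`, `models.ccs`, `verdicts.json` (per-patient
#' verdict, witness, failure note and slice localization), `metrics.json`
#' and `spearman.csv` (when labels are available), and `manifest.json`.
#' Reruns with the same configuration produce byte-identical metrics.
#'
#' @param rc A [run_config()].
#' @return Invisibly, a list with the feature table, scheme, verdicts
#'   data.frame and (if labelled) the metrics report.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "radformal_run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), radformal_error = function(e)
      .rf_stop("bad_input", "stage '%s' failed: %s", name,
               conditionMessage(e)))
    .rf_log(rc$verbose, "%s done in %.2fs", name,
            proc.time()[["elapsed"]] - s)
    r
  }

  table <- stage("features", {
    if (!is.null(rc$feature_csv)) read_feature_table(rc$feature_csv)
    else extract_cohort_features(read_nifti_cohort(rc$image_dir), rc$config)
  })
  write_feature_table(table, file.path(rc$out_dir, "features.csv"))

  scheme <- stage("discretize", {
    if (!is.null(rc$scheme_file)) read_binning_scheme(rc$scheme_file)
    else fit_bins(table)
  })
  write_binning_scheme(scheme, file.path(rc$out_dir, "binning_scheme.json"))
  levels <- assign_levels(table, scheme)
  utils::write.csv(levels, file.path(rc$out_dir, "levels.csv"),
                   row.names = FALSE)

  props <- stage("properties", {
    if (is.null(rc$property_file)) sts_property_set()
    else parse_properties(readChar(rc$property_file,
                                   file.size(rc$property_file),
                                   useBytes = TRUE))
  })

  pids <- unique(levels$patient_id)
  procs <- stage("model", lapply(pids, function(pid)
    build_process(to_action_sequence(
      levels[levels$patient_id == pid, , drop = FALSE]))))
  writeLines(write_ccs(procs), file.path(rc$out_dir, "models.ccs"), sep = "")

  checks <- stage("check", lapply(procs, function(p) {
    lts <- to_lts(p)
    chk <- check_patient(lts, props)
    loc <- localize(lts, props)
    list(check = chk, localization = loc)
  }))
  verdicts <- data.frame(
    patient_id = pids,
    verdict = vapply(checks, function(x) x$check$verdict, logical(1)),
    predicted = ifelse(vapply(checks, function(x) x$check$verdict,
                              logical(1)), "B", "A"),
    row.names = NULL)
  verdict_doc <- lapply(seq_along(pids), function(i) {
    chk <- checks[[i]]$check
    list(patient_id = pids[i], verdict = chk$verdict,
         witness = chk$witness, failure = chk$failure,
         localization = checks[[i]]$localization)
  })
  names(verdict_doc) <- pids
  jsonlite::write_json(verdict_doc, file.path(rc$out_dir, "verdicts.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  metrics <- NULL
  if (!is.null(rc$labels_csv)) {
    metrics <- stage("metrics", {
      labels <- read_labels(rc$labels_csv)
      missing <- setdiff(pids, names(labels))
      if (length(missing))
        .rf_stop("bad_input", "no label for patient(s): %s",
                 paste(missing, collapse = ", "))
      cm <- confusion_matrix(labels[pids],
                             stats::setNames(verdicts$predicted, pids))
      m <- classification_metrics(cm)
      cui <- clinical_utility(m)
      doc <- list(counts = unclass(cm),
                  raw = m[c("sensitivity", "specificity", "accuracy",
                            "ppv", "npv")],
                  display = m$display,
                  cui = cui[c("cui_positive", "cui_negative")],
                  cui_display = cui$display, cui_grades = as.list(cui$grades))
      jsonlite::write_json(doc, file.path(rc$out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(spearman_matrix(table),
                       file.path(rc$out_dir, "spearman.csv"))
      list(metrics = m, cui = cui, confusion = cm)
    })
  }

  manifest <- list(package = "radformal",
                   version = as.character(utils::packageVersion("radformal")),
                   r_version = R.version.string,
                   seed = rc$seed,
                   config_hash = .rf_config_hash(rc),
                   inputs = list(feature_csv = rc$feature_csv,
                                 image_dir = rc$image_dir,
                                 labels_csv = rc$labels_csv,
                                 property_file = rc$property_file,
                                 scheme_file = rc$scheme_file),
                   preprocess = unclass(rc$config),
                   n_patients = length(pids),
                   elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(manifest, file.path(rc$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .rf_log(rc$verbose, "pipeline finished in %.2fs", manifest$elapsed_s)
  invisible(list(table = table, scheme = scheme, verdicts = verdicts,
                 metrics = metrics))
}

#' Write a synthetic cohort to the pipeline's file formats
#'
#' Sequence-mode cohorts are written as `models.ccs` plus `labels.csv`;
#' image-mode cohorts as NIfTI `images/` + `masks/` directories plus
#' `labels.csv`, ready for [run_pipeline()].
#'
#' @param cohort A `radformal_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "radformal_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(
    patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    group = vapply(cohort$patients, `[[`, character(1), "group"))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  if (cohort$mode == "sequence") {
    procs <- lapply(cohort$patients, function(p) build_process(p$sequence))
    writeLines(write_ccs(procs), file.path(dir, "models.ccs"), sep = "")
  } else {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (p in cohort$patients) {
      sl <- p$stacks$slices
      dims <- dim(sl[[1]]$image$pixels)
      img <- array(0, c(dims, length(sl)))
      msk <- array(0L, c(dims, length(sl)))
      for (k in seq_along(sl)) {
        img[, , k] <- sl[[k]]$image$pixels
        msk[, , k] <- sl[[k]]$mask$pixels
      }
      sp <- c(sl[[1]]$image$spacing, 1)
      for (w in list(list(a = img, d = "images"), list(a = msk, d = "masks"))) {
        ni <- RNifti::asNifti(w$a, pixdim = sp)
        RNifti::writeNifti(ni, file.path(dir, w$d,
                                         paste0(p$patient_id, ".nii.gz")))
      }
    }
  }
  invisible(dir)
}
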