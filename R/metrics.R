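# Classification metrics with group B ("metastases / local recurrence") as
# the positive class, plus the clinical utility indices of Mitchell:
# CUI+ = sensitivity * PPV and CUI- = specificity * NPV, graded as
# excellent (>= 0.81), good (>= 0.64), satisfactory/fair (>= 0.49),
# poor (< 0.49) and very poor (<= 0.36).

#' Confusion matrix with group B as the positive class
#'
#' @param truth Character vector of true groups in \{"A", "B"\}; may be
#'   named by patient id.
#' @param predicted Predicted groups; when both vectors are named they are
#'   aligned by name.
#' @return Object of class `radformal_cm` with counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (!is.null(names(truth)) && !is.null(names(predicted))) {
    if (!setequal(names(truth), names(predicted)))
      .rf_stop("bad_input", "truth and predictions cover different patients")
    predicted <- predicted[names(truth)]
  }
  if (length(truth) != length(predicted))
    .rf_stop("bad_input", "truth and predictions have different lengths")
  if (!all(c(truth, predicted) %in% c("A", "B")))
    .rf_stop("bad_input", "labels must be 'A' or 'B'")
  structure(list(tp = sum(truth == "B" & predicted == "B"),
                 fp = sum(truth == "A" & predicted == "B"),
                 tn = sum(truth == "A" & predicted == "A"),
                 fn = sum(truth == "B" & predicted == "A")),
            class = "radformal_cm")
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `radformal_cm`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    .rf_stop("bad_input", "counts must be non-negative integers")
  structure(as.list(counts), class = "radformal_cm")
}

# Half-up rounding to the printed precision (raw values are kept alongside).
.rf_round_half_up <- function(x, digits) {
  ifelse(is.na(x), NA_real_,
         sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits)
}

#' Sensitivity, specificity, accuracy, PPV and NPV
#'
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' as an error. `$display` carries the values rounded half-up to two
#' decimals, the precision at which they are conventionally reported.
#'
#' @param cm A `radformal_cm`.
#' @return Object of class `radformal_metrics`: raw `sensitivity`,
#'   `specificity`, `accuracy`, `ppv`, `npv`, the counts, and a `display`
#'   list of rounded values.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "radformal_cm"))
  div <- function(num, den) if (den > 0) num / den else NA_real_
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  m <- list(sensitivity = div(cm$tp, cm$tp + cm$fn),
            specificity = div(cm$tn, cm$tn + cm$fp),
            accuracy = div(cm$tp + cm$tn, n),
            ppv = div(cm$tp, cm$tp + cm$fp),
            npv = div(cm$tn, cm$tn + cm$fn))
  m$counts <- cm
  m$display <- lapply(m[1:5], .rf_round_half_up, digits = 2)
  structure(m, class = "radformal_metrics")
}

.rf_cui_grade <- function(cui) {
  if (is.na(cui)) return(NA_character_)
  if (cui >= 0.81) return("excellent")
  if (cui >= 0.64) return("good")
  if (cui >= 0.49) return("satisfactory/fair")
  # the conventional "poor < 0.49" and "very poor <= 0.36" bands overlap;
  # resolved by band ordering: very poor iff <= 0.36, else poor
  if (cui <= 0.36) return("very poor")
  "poor"
}

#' Clinical utility indices and their grades
#'
#' `CUI+ = sensitivity * PPV` measures case-finding utility and
#' `CUI- = specificity * NPV` screening utility; both are graded on the
#' standard bands (see above). Undefined inputs give undefined indices.
#'
#' @param metrics A [classification_metrics()] report.
#' @return List with raw `cui_positive`, `cui_negative`, their `grades`,
#'   and 3-decimal `display` values.
#' @export
clinical_utility <- function(metrics) {
  stopifnot(inherits(metrics, "radformal_metrics"))
  cui_pos <- metrics$sensitivity * metrics$ppv
  cui_neg <- metrics$specificity * metrics$npv
  list(cui_positive = cui_pos, cui_negative = cui_neg,
       grades = c(cui_positive = .rf_cui_grade(cui_pos),
                  cui_negative = .rf_cui_grade(cui_neg)),
       display = list(cui_positive = .rf_round_half_up(cui_pos, 3),
                      cui_negative = .rf_round_half_up(cui_neg, 3)))
}

#' Spearman rank intercorrelation of the five features
#'
#' Pairwise Spearman correlation over all slices of the cohort, with
#' average ranks for ties. Entries involving a constant column are
#' undefined (`NA`).
#'
#' @param table Feature table.
#' @return Symmetric 5 x 5 correlation matrix.
#' @export
spearman_matrix <- function(table) {
  validate_feature_table(table)
  if (nrow(table) < 3L)
    .rf_stop("bad_input", "need at least 3 rows for rank correlation")
  suppressWarnings(stats::cor(as.matrix(table[, .rf_feature_columns]),
                              method = "spearman"))
}

#' @export
print.radformal_cm <- function(x, ...) {
  cat("          predicted B  predicted A\n")
  cat(sprintf("actual B  %11d  %11d\n", x$tp, x$fn))
  cat(sprintf("actual A  %11d  %11d\n", x$fp, x$tn))
  invisible(x)
}

#' @export
print.radformal_metrics <- function(x, ...) {
  d <- x$display
  cat(sprintf("sensitivity %.2f  specificity %.2f  accuracy %.2f\n",
              d$sensitivity, d$specificity, d$accuracy))
  cat(sprintf("PPV %.2f  NPV %.2f\n", d$ppv, d$npv))
  invisible(x)
}
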