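#' Fit 3-level equal-width bins over a cohort feature table
#'
#' For each of the five features, the bin bounds are the cohort-wide minimum
#' and maximum over all slices of all patients, with interior edges at
#' min + (max-min)/3 and min + 2(max-min)/3. Fitting cohort-wide makes the
#' low/basal/up levels comparable across patients, which a property shared
#' by the whole cohort requires. A constant feature column is marked
#' degenerate and always maps to the middle level.
#'
#' @param table Feature table (see [read_feature_table()]).
#' @return An object of class `radformal_bins`: per feature, a list with
#'   `lower`, `upper`, `edges` (two interior edges) and `degenerate`.
#' @export
fit_bins <- function(table) {
  validate_feature_table(table)
  scheme <- lapply(.rf_feature_columns, function(col) {
    v <- table[[col]]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      .rf_stop("degenerate_input", "feature '%s' has fewer than 2 values", col)
    lo <- min(v); hi <- max(v)
    if (lo == hi)
      return(list(lower = lo, upper = hi, edges = c(lo, hi),
                  degenerate = TRUE))
    list(lower = lo, upper = hi,
         edges = c(lo + (hi - lo) / 3, lo + 2 * (hi - lo) / 3),
         degenerate = FALSE)
  })
  names(scheme) <- .rf_feature_columns
  structure(scheme, class = "radformal_bins")
}

.rf_level <- function(values, bin) {
  if (isTRUE(bin$degenerate)) return(rep(2L, length(values)))
  # Ties at an interior edge go to the upper bin; the maximum is level 3.
  # Values outside [lower, upper] (new data scored with a stored scheme)
  # are clamped into the extreme bins.
  lev <- 1L + (values >= bin$edges[1]) + (values >= bin$edges[2])
  as.integer(pmin(pmax(lev, 1L), 3L))
}

#' Map feature values to discrete levels 1..3
#'
#' Adds one `<feature>_level` integer column per feature: 1 = low,
#' 2 = basal, 3 = up. Values equal to an interior edge go to the upper bin;
#' values outside the fitted range are clamped.
#'
#' @param table Feature table.
#' @param scheme A [fit_bins()] scheme.
#' @return The table with five added `_level` columns.
#' @export
assign_levels <- function(table, scheme) {
  validate_feature_table(table)
  stopifnot(inherits(scheme, "radformal_bins"))
  for (col in .rf_feature_columns)
    table[[paste0(col, "_level")]] <- .rf_level(table[[col]], scheme[[col]])
  table
}

#' Build the action label for one feature level
#'
#' @param level Integer 1..3.
#' @param feature Feature name in the action alphabet (e.g. "meshsurface").
#' @return Character label of the form `b{level}of3{feature}`.
#' @export
action_label <- function(level, feature) {
  stopifnot(all(level %in% 1:3), all(feature %in% .rf_action_features))
  paste0("b", level, "of3", feature)
}

#' Turn a patient's levelled rows into an action sequence
#'
#' Emits, per slice in ascending `slice_index` order, the five actions in
#' the fixed order sphericity, kurtosis, skewness, elongation, meshsurface.
#'
#' @param rows Levelled rows of one patient ([assign_levels()] output).
#' @return An object of class `radformal_actionseq`: `patient_id`,
#'   `actions` (character, 5 per slice), `slice_ids` (one per action) and
#'   `slice_starts` (index of the first action of each slice).
#' @export
to_action_sequence <- function(rows) {
  if (nrow(rows) == 0L) .rf_stop("bad_input", "no rows for patient")
  pid <- unique(rows$patient_id)
  if (length(pid) != 1L)
    .rf_stop("bad_input", "rows span more than one patient")
  lev_cols <- paste0(.rf_action_to_column[.rf_action_features], "_level")
  miss <- setdiff(lev_cols, names(rows))
  if (length(miss))
    .rf_stop("bad_input", "missing level column(s): %s",
             paste(miss, collapse = ", "))
  rows <- rows[order(rows$slice_index), , drop = FALSE]
  actions <- character(0)
  slice_ids <- integer(0)
  for (i in seq_len(nrow(rows))) {
    levs <- as.integer(rows[i, lev_cols])
    if (any(is.na(levs)))
      .rf_stop("bad_input", "missing feature level in slice %d",
               rows$slice_index[i])
    actions <- c(actions, action_label(levs, .rf_action_features))
    slice_ids <- c(slice_ids, rep(rows$slice_index[i], 5L))
  }
  structure(list(patient_id = pid, actions = actions, slice_ids = slice_ids,
                 slice_starts = seq(1L, length(actions), by = 5L)),
            class = "radformal_actionseq")
}

#' Build an action sequence directly from a level matrix
#'
#' Convenience constructor used by the synthetic generator: `levels` is a
#' 5 x n_slices integer matrix whose rows follow the within-slice action
#' order (sphericity, kurtosis, skewness, elongation, meshsurface).
#'
#' @param patient_id Identifier.
#' @param levels Integer matrix in \{1,2,3\}, 5 rows.
#' @param slice_ids Optional slice indices (default 1..n_slices).
#' @return A `radformal_actionseq`.
#' @export
action_sequence_from_levels <- function(patient_id, levels,
                                        slice_ids = seq_len(ncol(levels))) {
  stopifnot(nrow(levels) == 5L, all(levels %in% 1:3),
            length(slice_ids) == ncol(levels))
  actions <- as.vector(vapply(seq_len(ncol(levels)), function(j)
    action_label(levels[, j], .rf_action_features), character(5L)))
  structure(list(patient_id = patient_id, actions = actions,
                 slice_ids = rep(as.integer(slice_ids), each = 5L),
                 slice_starts = seq(1L, length(actions), by = 5L)),
            class = "radformal_actionseq")
}

#' Persist / load a binning scheme as JSON
#'
#' @param scheme A [fit_bins()] scheme.
#' @param path JSON file path.
#' @export
write_binning_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "radformal_bins"))
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binning_scheme
#' @export
read_binning_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(.rf_feature_columns, names(raw))
  if (length(miss))
    .rf_stop("bad_input", "scheme lacks feature(s): %s",
             paste(miss, collapse = ", "))
  structure(raw[.rf_feature_columns], class = "radformal_bins")
}
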