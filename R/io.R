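#' Read an image/mask NIfTI pair as a per-slice stack
#'
#' Volumes are read with RNifti; slices are taken along the last axis and
#' the in-plane pixel spacing is read from the header. Image and mask must
#' have identical dimensions.
#'
#' @param image_path Path to the image volume (.nii / .nii.gz).
#' @param mask_path Path to the binary mask volume.
#' @param patient_id Identifier; defaults to the image file name without
#'   extensions.
#' @return A patient stack suitable for [extract_cohort_features()].
#' @export
read_nifti_patient <- function(image_path, mask_path, patient_id = NULL) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk)))
    .rf_stop("bad_input", "image and mask dimensions differ for '%s'",
             image_path)
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  spacing <- RNifti::pixdim(img)[1:2]
  dims <- dim(img)
  n_slices <- if (length(dims) >= 3L) dims[3] else 1L
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    ip <- if (length(dims) >= 3L) img[, , k] else img[, ]
    mp <- if (length(dims) >= 3L) msk[, , k] else msk[, ]
    slices[[k]] <- list(image = slice_image(ip, spacing, k),
                        mask = slice_mask(mp, spacing))
  }
  list(patient_id = patient_id, slices = slices)
}

#' Read a cohort of NIfTI image/mask pairs from a directory
#'
#' Expects `images/` and `masks/` subdirectories containing identically
#' named volumes; the file name (without extension) is the patient id.
#'
#' @param dir Cohort directory.
#' @return List of patient stacks for [extract_cohort_features()].
#' @export
read_nifti_cohort <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"),
                          pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(imgs) == 0L)
    .rf_stop("bad_input", "no NIfTI images found under %s/images", dir)
  lapply(imgs, function(ip) {
    mp <- file.path(dir, "masks", basename(ip))
    if (!file.exists(mp))
      .rf_stop("bad_input", "missing mask for image '%s'", basename(ip))
    read_nifti_patient(ip, mp)
  })
}

#' Read / write the per-slice feature table
#'
#' The CSV has header
#' `patient_id,slice_index,kurtosis,skewness,elongation,sphericity,mesh_surface`.
#' Values read from CSV are taken as-is (the ingestion path bypasses image
#' preprocessing entirely).
#'
#' @param path CSV file path.
#' @return `read_feature_table()`: validated `data.frame`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_feature_table(df)
  df
}

#' @rdname read_feature_table
#' @param table Feature table `data.frame`.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Validate a feature table
#'
#' Checks required columns, uniqueness of (patient_id, slice_index) and that
#' every patient has at least one row.
#'
#' @param table A `data.frame`.
#' @return The table, invisibly.
#' @export
validate_feature_table <- function(table) {
  req <- c("patient_id", "slice_index", .rf_feature_columns)
  miss <- setdiff(req, names(table))
  if (length(miss))
    .rf_stop("bad_input", "feature table lacks column(s): %s",
             paste(miss, collapse = ", "))
  key <- paste(table$patient_id, table$slice_index)
  if (anyDuplicated(key))
    .rf_stop("bad_input", "duplicated (patient_id, slice_index) rows")
  invisible(table)
}

#' Read a cohort label file
#'
#' CSV with header `patient_id,group`, group in \{A, B\}; group B is the
#' positive class (metastases / local recurrence).
#'
#' @param path CSV file path.
#' @return Named character vector of groups, names = patient ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "group") %in% names(df)))
    .rf_stop("bad_input", "labels file needs columns patient_id, group")
  if (!all(df$group %in% c("A", "B")))
    .rf_stop("bad_input", "labels must be 'A' or 'B'")
  stats::setNames(df$group, df$patient_id)
}
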