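#' Volumetric data containers
#'
#' `hv_volume()` wraps a 3D numeric array together with its voxel geometry;
#' `hv_labelmap()` holds an integer parcellation on the same grid plus a
#' code table mapping region codes to names; `hv_mask()` holds a logical
#' grid. All three assume the co-registered voxel space of the T1-weighted
#' acquisition: no resampling is ever performed, masks and labels are
#' interpreted on the parent grid with 0-based world-agnostic indices.
#'
#' @param data 3D numeric array of intensities.
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return An object of class `hv_volume`.
#' @export
hv_volume <- function(data, voxel_size = c(0.75, 0.75, 0.75), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("hv_volume: `data` must be a 3D array, got ", length(dim(data)), "D", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("hv_volume: intensities must be finite", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("hv_volume: `voxel_size` must be 3 strictly positive values (mm)", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("hv_volume: `affine` must be 4x4", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "hv_volume")
}

#' @export
print.hv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hv_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm; range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.hv_volume <- function(x) dim(x$data)

#' Construct a label map
#'
#' @param labels 3D array of non-negative integer region codes.
#' @param code_table named integer vector or data frame mapping codes to
#'   region names (defaults to [aseg_code_table()]).
#' @return An object of class `hv_labelmap` with fields `labels`,
#'   `code_table` and `unknown_codes` (codes present in the grid but absent
#'   from the table).
#' @export
hv_labelmap <- function(labels, code_table = aseg_code_table()) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("hv_labelmap: `labels` must be a 3D array", call. = FALSE)
  if (any(labels != round(labels)) || any(labels < 0))
    stop("hv_labelmap: labels must be non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  ct <- as_code_table(code_table)
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, c(0L, ct$code))
  if (length(unknown))
    warning("hv_labelmap: codes not in code table flagged unknown: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, code_table = ct, unknown_codes = unknown),
            class = "hv_labelmap")
}

#' @export
dim.hv_labelmap <- function(x) dim(x$labels)

as_code_table <- function(code_table) {
  if (is.data.frame(code_table)) {
    stopifnot(all(c("code", "region") %in% names(code_table)))
    tibble::tibble(code = as.integer(code_table$code),
                   region = as.character(code_table$region))
  } else {
    tibble::tibble(code = as.integer(code_table),
                   region = names(code_table))
  }
}

#' Default FreeSurfer-style region code table
#'
#' The subset of the aseg/aparc convention this pipeline relies on:
#' hippocampi, cerebral white matter, cerebellum, and the cortical regions
#' excluded during vessel refinement (temporal, supramarginal,
#' orbitofrontal). Overridable wherever a `code_table` argument exists.
#'
#' @return A tibble with columns `code`, `region`.
#' @export
aseg_code_table <- function() {
  tibble::tribble(
    ~code, ~region,
    2L,    "Left-Cerebral-White-Matter",
    41L,   "Right-Cerebral-White-Matter",
    17L,   "Left-Hippocampus",
    53L,   "Right-Hippocampus",
    7L,    "Left-Cerebellum-White-Matter",
    8L,    "Left-Cerebellum-Cortex",
    46L,   "Right-Cerebellum-White-Matter",
    47L,   "Right-Cerebellum-Cortex",
    1009L, "ctx-lh-inferiortemporal",
    1015L, "ctx-lh-middletemporal",
    1030L, "ctx-lh-superiortemporal",
    1033L, "ctx-lh-temporalpole",
    1034L, "ctx-lh-transversetemporal",
    1031L, "ctx-lh-supramarginal",
    1012L, "ctx-lh-lateralorbitofrontal",
    1014L, "ctx-lh-medialorbitofrontal",
    2009L, "ctx-rh-inferiortemporal",
    2015L, "ctx-rh-middletemporal",
    2030L, "ctx-rh-superiortemporal",
    2033L, "ctx-rh-temporalpole",
    2034L, "ctx-rh-transversetemporal",
    2031L, "ctx-rh-supramarginal",
    2012L, "ctx-rh-lateralorbitofrontal",
    2014L, "ctx-rh-medialorbitofrontal"
  )
}

#' Region codes excluded during vessel-mask refinement
#'
#' White matter, cerebellum, temporal, supramarginal and orbitofrontal
#' regions: vesselness detections inside these are discarded before the
#' hippocampus-connectivity step.
#'
#' @return Integer vector of codes from [aseg_code_table()].
#' @export
default_excluded_codes <- function() {
  ct <- aseg_code_table()
  ct$code[!ct$region %in% c("Left-Hippocampus", "Right-Hippocampus")]
}

#' Construct a binary mask
#'
#' @param mask 3D logical (or 0/1) array.
#' @return An object of class `hv_mask`.
#' @export
hv_mask <- function(mask) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("hv_mask: `mask` must be a 3D array", call. = FALSE)
  if (is.numeric(mask) && !all(mask %in% c(0, 1)))
    stop("hv_mask: numeric mask must be 0/1", call. = FALSE)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask), class = "hv_mask")
}

#' @export
dim.hv_mask <- function(x) dim(x$mask)

# shape compatibility guard used before any cross-volume operation
check_same_grid <- function(a, b, what_a = "first", what_b = "second") {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db))
    stop(sprintf("grid shape mismatch: %s is %s, %s is %s",
                 what_a, paste(da, collapse = "x"),
                 what_b, paste(db, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving intensities and voxel geometry.
#' `load_volume()` rejects non-3D images; `load_labelmap()` additionally
#' requires integer-valued data and can check alignment against a reference
#' grid.
#'
#' @param path path to a NIfTI-1/2 file.
#' @return `load_volume()`: an [hv_volume]; `load_labelmap()`: an
#'   [hv_labelmap]; `load_mask()`: an [hv_mask].
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop("load_volume: file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("load_volume: cannot read NIfTI file ",
                                           path, ": ", conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("load_volume: ", path, " is ", length(d), "D; a 3D volume is required",
         call. = FALSE)
  pd <- RNifti::pixdim(img)[seq_len(3)]
  hv_volume(array(as.numeric(img), dim = d), voxel_size = pd,
            affine = unclass(RNifti::xform(img)))
}

#' @rdname load_volume
#' @param volume an [hv_volume], [hv_labelmap] or [hv_mask] to write.
#' @export
save_volume <- function(volume, path) {
  arr <- if (inherits(volume, "hv_volume")) volume$data
         else if (inherits(volume, "hv_labelmap")) volume$labels
         else if (inherits(volume, "hv_mask")) volume$mask * 1L
         else stop("save_volume: unsupported object", call. = FALSE)
  vs <- if (inherits(volume, "hv_volume")) volume$voxel_size else c(0.75, 0.75, 0.75)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname load_volume
#' @param code_table mapping of codes to region names.
#' @param reference optional object whose grid the label map must match.
#' @export
load_labelmap <- function(path, code_table = aseg_code_table(), reference = NULL) {
  v <- load_volume(path)
  if (any(v$data != round(v$data)))
    stop("load_labelmap: ", path, " contains non-integer values; not a label map",
         call. = FALSE)
  if (!is.null(reference)) check_same_grid(reference, v, "reference", path)
  hv_labelmap(v$data, code_table)
}

#' @rdname load_volume
#' @export
load_mask <- function(path, reference = NULL) {
  v <- load_volume(path)
  if (!all(v$data %in% c(0, 1)))
    stop("load_mask: ", path, " is not binary", call. = FALSE)
  if (!is.null(reference)) check_same_grid(reference, v, "reference", path)
  hv_mask(v$data == 1)
}

#' Systemic variable names used in the mediation grid
#'
#' The 23 resting systemic physiology and cardiometabolic parameters:
#' blood pressure (SBP, DBP, beat-to-beat SBP_SD, LF-BPV), adiposity
#' (waist, BMI), autonomic function (HR, SDNN, HF-HRV, CO, PEP, BRS),
#' vascular structure/function (VOP%, PWV, IMT), metabolic markers
#' (glucose, insulin, LDL, vLDL, A1C) and inflammation/endothelial
#' activation (IL-6, ICAM-1, VCAM-1).
#'
#' @return Character vector of 23 column names.
#' @export
systemic_variables <- function() {
  c("sbp", "dbp", "waist", "bmi", "hr", "sdnn", "hf_hrv", "co", "pep",
    "vop_pct", "pwv", "imt", "glucose", "insulin", "ldl", "vldl", "il6",
    "icam1", "vcam1", "a1c", "sbp_sd", "lf_bpv", "brs")
}

#' Variables log(1+x)-transformed before mediation by default
#' @return Character vector.
#' @export
log1p_variables <- function() c("insulin", "il6")

subject_required_columns <- function(systemic = systemic_variables()) {
  c("subject_id", "age", "sex", "icv",
    "hippo_vol_left", "hippo_vol_right",
    "vessel_vol_left", "vessel_vol_right",
    "vessel_si_left", "vessel_si_right",
    systemic)
}

#' Read a per-subject table
#'
#' Reads the cohort CSV: one row per subject with covariates (age, sex
#' coded 0/1, ICV in mm^3), hemisphere-specific hippocampal volumes and
#' vessel metrics, and the systemic variables. Empty cells become `NA`
#' (explicit missing), never zero. Derived total-hemisphere columns are
#' added via [derive_totals()].
#'
#' @param path CSV file with a header row.
#' @param systemic character vector of required systemic column names.
#' @return A tibble, one row per subject.
#' @export
read_subject_table <- function(path, systemic = systemic_variables()) {
  if (!file.exists(path))
    stop("read_subject_table: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- subject_required_columns(systemic)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("read_subject_table: required columns absent: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- tibble::as_tibble(df)
  num_cols <- setdiff(required, "subject_id")
  df[num_cols] <- lapply(df[num_cols], function(x) suppressWarnings(as.numeric(x)))
  bad_vol <- c("icv", "hippo_vol_left", "hippo_vol_right")
  for (cl in bad_vol) {
    if (any(!is.na(df[[cl]]) & df[[cl]] <= 0))
      stop("read_subject_table: non-positive values in ", cl, call. = FALSE)
  }
  derive_totals(df)
}

#' Add total-hemisphere columns to a subject table
#'
#' Volumes sum across hemispheres; vessel SI totals are vessel-volume-
#' weighted means of the hemisphere SIs (the mean over the combined vessel
#' mask), falling back to the unweighted mean when volumes are missing.
#'
#' @param df subject tibble with the hemisphere-specific columns.
#' @return The tibble with `hippo_vol_total`, `vessel_vol_total`,
#'   `vessel_si_total` added (overwritten if present).
#' @export
derive_totals <- function(df) {
  df$hippo_vol_total <- df$hippo_vol_left + df$hippo_vol_right
  df$vessel_vol_total <- df$vessel_vol_left + df$vessel_vol_right
  w_l <- df$vessel_vol_left; w_r <- df$vessel_vol_right
  weighted <- (df$vessel_si_left * w_l + df$vessel_si_right * w_r) / (w_l + w_r)
  fallback <- (df$vessel_si_left + df$vessel_si_right) / 2
  df$vessel_si_total <- ifelse(is.finite(weighted), weighted, fallback)
  df
}
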