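CMH2O_PER_MMHG <- 1.36

#' Read a CT volume from NIfTI
#'
#' Reads a (optionally gzipped) NIfTI volume and wraps it as a
#' [ct_volume()], taking voxel spacing from the NIfTI pixdim. HU are assumed
#' already rescaled.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_ct_nifti <- function(path) {
  if (!file.exists(path)) stop("CT file not found: ", path)
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3])
}

#' Read a lung mask from NIfTI
#'
#' Nonzero voxels are inside the mask.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [lung_mask()].
#' @export
read_mask_nifti <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  lung_mask(array(as.numeric(img) != 0, dim = dim(img)))
}

#' Write a CT volume or mask to NIfTI
#'
#' @param x A [ct_volume()] or [lung_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing (mm); taken from `x` for CT volumes.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "ct_volume")) {
    arr <- x$hu; spacing <- x$spacing
  } else if (inherits(x, "lung_mask")) {
    arr <- array(as.integer(x$inside), dim = dim(x$inside))
    if (is.null(spacing)) spacing <- c(1, 1, 1)
  } else stop("x must be a ct_volume or lung_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_columns <- function(df, need, what) {
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop(what, " must have columns: ", paste(need, collapse = ", "),
         if (is.data.frame(df))
           paste0(" (found: ", paste(names(df), collapse = ", "), ")")
         else "")
  invisible(df)
}

#' Read a pressure-volume table
#'
#' CSV with columns `pressure_cmH2O`, `volume`, `compartment`, `condition`,
#' `phase` (UTF-8, header row, dot decimal). Pressures recorded in mmHg can
#' be converted on read (1 mmHg = 1.36 cmH2O).
#'
#' @param path CSV path.
#' @param pressure_unit Unit of the pressure column in the file.
#' @return A PV data frame with pressures in cmH2O.
#' @export
read_pv_table <- function(path, pressure_unit = c("cmH2O", "mmHg")) {
  pressure_unit <- match.arg(pressure_unit)
  if (!file.exists(path)) stop("PV table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("pressure_cmH2O", "volume", "compartment"),
                "PV table")
  if (pressure_unit == "mmHg")
    df$pressure_cmH2O <- df$pressure_cmH2O * CMH2O_PER_MMHG
  df
}

#' Read a long-format titration table
#'
#' CSV with columns `subject`, `phase`, `peep_cmH2O`, `endpoint`, `value`
#' (optional `condition`). PEEP recorded in mmHg can be converted on read.
#'
#' @inheritParams read_pv_table
#' @return A titration data frame with PEEP in cmH2O.
#' @export
read_titration_table <- function(path, pressure_unit = c("cmH2O", "mmHg")) {
  pressure_unit <- match.arg(pressure_unit)
  if (!file.exists(path)) stop("titration table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("peep_cmH2O", "endpoint", "value"), "titration table")
  if (pressure_unit == "mmHg")
    df$peep_cmH2O <- df$peep_cmH2O * CMH2O_PER_MMHG
  df
}

#' Packaged porcine titration medians (descending phase)
#'
#' Median descending-phase values of the cardio-respiratory and CT endpoints
#' at PEEP 5, 12, 17, 22 and 27 cmH2O under an intra-abdominal pressure of
#' 27 cmH2O, for healthy and oleic-acid-injured lungs, transcribed from a
#' published porcine intra-abdominal-hypertension PEEP-titration experiment.
#' Ships so the best-PEEP selector can be exercised offline; see
#' `inst/extdata/titration_medians_descending.csv`.
#'
#' @param condition Optional filter, `"healthy"` or `"injured"`.
#' @return Data frame with columns `condition`, `phase`, `peep_cmH2O`,
#'   `endpoint`, `value` (one pseudo-subject per condition, phase
#'   `descending`).
#' @export
titration_medians <- function(condition = NULL) {
  path <- system.file("extdata", "titration_medians_descending.csv",
                      package = "peepct", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$phase <- "descending"
  df$subject <- paste0("median_", df$condition)
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("healthy", "injured"))
    df <- df[df$condition == condition, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Standard PEEP titration targets
#'
#' The endpoint/direction pairs used for best-PEEP selection: oxygenation
#' and gas volume are maximized, elastances and adverse CT compartments are
#' minimized, cardiac output is maximized.
#'
#' @return Data frame with columns `target` (endpoint name) and `direction`.
#' @export
titration_targets <- function() {
  data.frame(
    target = c("pf_ratio", "E_rs", "E_W", "E_L", "cardiac_output",
               "gas_volume_mL", "overdistended_pct",
               "normally_aerated_pct", "atelectatic_pct"),
    direction = c("highest", "lowest", "lowest", "lowest", "highest",
                  "highest", "lowest", "highest", "lowest")
  )
}
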