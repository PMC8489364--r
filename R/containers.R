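#' CT volume container
#'
#' A 3-D scalar field of Hounsfield units with voxel spacing and the supine
#' dependent-axis convention used throughout the package: axis 3 is the
#' ventro-dorsal axis and index 1 along it is the most ventral voxel, so
#' larger indices are more dependent. HU are assumed already rescaled
#' (slope/intercept applied).
#'
#' @param hu 3-D numeric array of Hounsfield units (finite).
#' @param spacing Numeric vector of 3 voxel edge lengths (mm), all > 0.
#' @param dependent_axis Index of the dependent axis (fixed convention: 3).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(hu, spacing = c(1, 1, 1), dependent_axis = 3L) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    stop("hu must be a 3-D array")
  if (!all(is.finite(hu))) stop("hu must be finite everywhere")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive lengths (mm)")
  if (!identical(as.integer(dependent_axis), 3L))
    stop("dependent_axis is fixed at 3 (supine convention)")
  structure(list(hu = hu, spacing = as.numeric(spacing),
                 dependent_axis = 3L),
            class = "ct_volume")
}

#' Lung mask container
#'
#' A binary field congruent with a [ct_volume()], marking lung voxels. Mask
#' creation (segmentation) is upstream of this package; phantoms carry their
#' own masks.
#'
#' @param inside 3-D logical array; must contain at least one `TRUE`.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(inside) {
  if (!is.array(inside) || length(dim(inside)) != 3L)
    stop("mask must be a 3-D array")
  inside <- inside & TRUE  # coerce to logical, preserving dim
  if (anyNA(inside)) stop("mask must not contain NA")
  if (!any(inside)) stop("mask must be non-empty")
  structure(list(inside = inside), class = "lung_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$hu), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "),
      " mm, HU range [", round(min(x$hu)), ", ", round(max(x$hu)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat("<lung_mask> ", paste(dim(x$inside), collapse = " x "),
      " voxels, ", sum(x$inside), " in mask\n", sep = "")
  invisible(x)
}

check_congruent <- function(ct, mask) {
  if (!inherits(ct, "ct_volume")) stop("ct must be a ct_volume")
  if (!inherits(mask, "lung_mask")) stop("mask must be a lung_mask")
  if (!identical(dim(ct$hu), dim(mask$inside)))
    stop("CT volume and mask shapes differ: (",
         paste(dim(ct$hu), collapse = ", "), ") vs (",
         paste(dim(mask$inside), collapse = ", "), ")")
  invisible(TRUE)
}
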