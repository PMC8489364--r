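#' @name aeration-compartments
#' @title Hounsfield-unit aeration compartments
#' @description
#' Lung voxels are classified into four aeration compartments by CT density:
#' overdistended (-1000 to -901 HU), normally aerated (-900 to -501 HU),
#' poorly aerated (-500 to -101 HU) and non-aerated atelectatic tissue
#' (-100 to 200 HU). In-mask voxels outside the \[-1000, 200\] window are
#' reported as excluded. Internally the bins are half-open with
#' lower-inclusive edges at -900 / -500 / -100, which reproduces the integer
#' ranges exactly while staying well defined for non-integer HU.
NULL

COMPARTMENTS <- c("overdistended", "normally_aerated",
                  "poorly_aerated", "atelectatic")
HU_WINDOW <- c(-1000, 200)
HU_EDGES <- c(-900, -500, -100)

#' Classify lung voxels into aeration compartments
#'
#' Assigns each in-mask voxel to one of the four HU aeration compartments
#' (see [aeration-compartments]) or to `excluded` when its HU lies outside
#' the \[-1000, 200\] window.
#'
#' @param ct A [ct_volume()].
#' @param mask A [lung_mask()] congruent with `ct`.
#' @return An integer array of the same shape: 0 outside the mask, 1-4 for
#'   overdistended / normally aerated / poorly aerated / atelectatic, 5 for
#'   in-mask voxels outside the HU window. The compartment names are attached
#'   as attribute `compartments`.
#' @export
classify_voxels <- function(ct, mask) {
  check_congruent(ct, mask)
  labels <- array(0L, dim = dim(ct$hu))
  idx <- which(mask$inside)
  hu <- ct$hu[idx]
  lab <- rep.int(5L, length(idx))
  inwin <- hu >= HU_WINDOW[1] & hu <= HU_WINDOW[2]
  lab[inwin] <- 1L + findInterval(hu[inwin], HU_EDGES)
  labels[idx] <- lab
  attr(labels, "compartments") <- c(COMPARTMENTS, "excluded")
  labels
}

#' Quantify aeration from classified voxels
#'
#' Computes per-compartment volumes and fractions plus gas volume and tissue
#' mass, using the standard quantitative-CT linear gas/tissue mixture: voxel
#' gas fraction `clamp(-HU/1000, 0, 1)`, tissue volume fraction
#' `1 - gas fraction`, tissue density `clamp((HU+1000)/1000, 0, 1.2)` g/mL.
#' Fractions are percentages of the included (in-window) volume and sum
#' to 100; gas volume plus tissue volume equals the included volume by
#' construction.
#'
#' @param ct A [ct_volume()].
#' @param mask A [lung_mask()] congruent with `ct`.
#' @param labels Optional label array from [classify_voxels()]; computed if
#'   missing.
#' @return An object of class `aeration_summary`: a list with
#'   `compartments` (data frame of compartment, volume_mL, fraction_pct),
#'   `excluded_volume_mL`, `mask_volume_mL`, `total_lung_volume_L`
#'   (included volume), `gas_volume_mL`, `tissue_volume_mL`,
#'   `tissue_mass_g` and `voxel_volume_mL`.
#' @examples
#' hu <- array(c(-950, -700, -300, 0, 0, 0, 0, 0), dim = c(2, 2, 2))
#' ct <- ct_volume(hu, spacing = c(10, 10, 10))  # 1 mL voxels
#' msk <- lung_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), dim = c(2, 2, 2)))
#' quantify_aeration(ct, msk)
#' @export
quantify_aeration <- function(ct, mask, labels = NULL) {
  check_congruent(ct, mask)
  if (is.null(labels)) labels <- classify_voxels(ct, mask)
  if (!identical(dim(labels), dim(ct$hu)))
    stop("labels shape does not match the volume")
  vox_mL <- prod(ct$spacing) / 1000
  idx <- which(mask$inside)
  lab <- labels[idx]
  hu <- ct$hu[idx]
  counts <- tabulate(lab, nbins = 5L)
  comp_vol <- counts[1:4] * vox_mL
  excl_vol <- counts[5] * vox_mL
  n_inc <- sum(counts[1:4])
  inc <- lab <= 4L
  gas_frac <- pmin(pmax(-hu[inc] / 1000, 0), 1)
  dens <- pmin(pmax((hu[inc] + 1000) / 1000, 0), 1.2)
  gas_mL <- sum(gas_frac) * vox_mL
  tis_mL <- sum(1 - gas_frac) * vox_mL
  structure(list(
    compartments = data.frame(
      compartment = COMPARTMENTS,
      volume_mL = comp_vol,
      fraction_pct = if (n_inc > 0) 100 * counts[1:4] / n_inc else
        rep(NA_real_, 4)
    ),
    excluded_volume_mL = excl_vol,
    mask_volume_mL = length(idx) * vox_mL,
    total_lung_volume_L = n_inc * vox_mL / 1000,
    gas_volume_mL = gas_mL,
    tissue_volume_mL = tis_mL,
    tissue_mass_g = sum(dens) * vox_mL,
    voxel_volume_mL = vox_mL
  ), class = "aeration_summary")
}

#' @export
print.aeration_summary <- function(x, digits = 3, ...) {
  cat("Lung aeration summary\n")
  cat(sprintf("  total lung volume: %.3f L  (gas %.0f mL, tissue mass %.0f g)\n",
              x$total_lung_volume_L, x$gas_volume_mL, x$tissue_mass_g))
  df <- x$compartments
  df$volume_mL <- round(df$volume_mL, digits)
  df$fraction_pct <- round(df$fraction_pct, digits)
  print(df, row.names = FALSE)
  if (x$excluded_volume_mL > 0)
    cat(sprintf("  excluded (outside [-1000, 200] HU): %.1f mL\n",
                x$excluded_volume_mL))
  invisible(x)
}

#' Partition the lung into dorso-ventral segments and left/right sides
#'
#' Cuts the mask's bounding extent along the dependent axis into
#' `n_segments` equal-thickness slabs (ventral, medial, dorsal for the
#' default 3). When the extent is not divisible, the remainder voxels are
#' assigned to the ventral-most slabs first (e.g. depth 31 gives 11/10/10).
#' Sides are split left/right at the midline of the mask's bounding box on
#' axis 1; the midline voxel (odd extents) goes to the left side.
#'
#' @param ct A [ct_volume()] (carries the dependent-axis convention).
#' @param mask A [lung_mask()] congruent with `ct`.
#' @param n_segments Number of dorso-ventral slabs (default 3).
#' @return A list of class `segment_partition` with integer arrays `segment`
#'   (0 outside mask, 1 = ventral-most slab .. `n_segments` = dorsal-most)
#'   and `side` (0 outside mask, 1 = left, 2 = right), plus `segment_names`.
#' @export
partition_segments <- function(ct, mask, n_segments = 3L) {
  check_congruent(ct, mask)
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  dims <- dim(mask$inside)
  zin <- which(apply(mask$inside, 3, any))
  z0 <- min(zin); z1 <- max(zin)
  depth <- z1 - z0 + 1L
  if (depth < n_segments)
    stop("mask extent along the dependent axis (", depth,
         " voxels) is thinner than n_segments (", n_segments, ")")
  base <- depth %/% n_segments
  sizes <- base + (seq_len(n_segments) <= depth %% n_segments)
  seg_of_z <- rep.int(seq_len(n_segments), sizes)  # ventral-first remainder
  seg_plane <- integer(dims[3])
  seg_plane[z0:z1] <- seg_of_z
  segment <- array(rep(seg_plane, each = dims[1] * dims[2]), dim = dims)
  segment[!mask$inside] <- 0L

  xin <- which(apply(mask$inside, 1, any))
  mid <- (min(xin) + max(xin)) %/% 2L
  side_line <- ifelse(seq_len(dims[1]) <= mid, 1L, 2L)
  side <- array(rep(side_line, times = dims[2] * dims[3]), dim = dims)
  side[!mask$inside] <- 0L

  seg_names <- if (n_segments == 3L) c("ventral", "medial", "dorsal") else
    paste0("segment", seq_len(n_segments))
  structure(list(segment = segment, side = side, segment_names = seg_names),
            class = "segment_partition")
}

#' Whole-lung and segmental aeration analysis
#'
#' Runs [classify_voxels()] and [quantify_aeration()] on the whole lung and
#' on every dorso-ventral segment and left/right side from
#' [partition_segments()], returning a tidy table.
#'
#' @param ct A [ct_volume()].
#' @param mask A [lung_mask()] congruent with `ct`.
#' @param n_segments Number of dorso-ventral slabs (default 3).
#' @return A list of class `aeration_analysis` with elements `whole`
#'   (an `aeration_summary`) and `table` (data frame with columns
#'   `segment` in whole/ventral/medial/dorsal, `side` in all/left/right,
#'   `compartment`, `volume_mL`, `fraction_pct`, plus per-scope
#'   `gas_volume_mL` and `tissue_mass_g` repeated on each row).
#' @export
aeration_analysis <- function(ct, mask, n_segments = 3L) {
  labels <- classify_voxels(ct, mask)
  part <- partition_segments(ct, mask, n_segments)
  scopes <- list(list(segment = "whole", side = "all", keep = mask$inside))
  for (s in seq_along(part$segment_names)) {
    seg_keep <- part$segment == s
    scopes[[length(scopes) + 1L]] <-
      list(segment = part$segment_names[s], side = "all", keep = seg_keep)
    for (sd in 1:2)
      scopes[[length(scopes) + 1L]] <-
        list(segment = part$segment_names[s],
             side = c("left", "right")[sd],
             keep = seg_keep & part$side == sd)
  }
  rows <- lapply(scopes, function(sc) {
    if (!any(sc$keep)) return(NULL)
    sm <- quantify_aeration(ct, lung_mask(sc$keep), labels)
    cbind(data.frame(segment = sc$segment, side = sc$side),
          sm$compartments,
          data.frame(gas_volume_mL = sm$gas_volume_mL,
                     tissue_mass_g = sm$tissue_mass_g))
  })
  whole <- quantify_aeration(ct, mask, labels)
  structure(list(whole = whole, table = do.call(rbind, rows)),
            class = "aeration_analysis")
}
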