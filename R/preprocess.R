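#' Fast bias-field correction from low spatial frequencies
#'
#' Estimates multiplicative brightness inhomogeneity as the low-spatial-
#' frequency component of the image and divides it out.  The field is a
#' large box mean (radius 30 mm by default) computed over a rough head mask
#' (whole-image Otsu foreground) with out-of-mask voxels ignored, and the
#' result is rescaled by the in-mask field mean so overall brightness is
#' preserved.  Restricting the field to the head mask keeps near-zero
#' background out of the divisor, so air stays dark instead of being
#' amplified to tissue level at the head boundary.  Voxels whose window
#' contains no head tissue are left unchanged.  This is a rough estimate --
#' enough to stabilise the marker generation downstream, not a substitute
#' for model-based correction -- and the step is optional for human scans.
#'
#' @param v a [vol3()] with positive intensities somewhere.
#' @param radius_mm box radius of the smoothing kernel in mm.
#' @return A bias-corrected `vol3` on the same grid.
#' @export
correct_bias <- function(v, radius_mm = 30) {
  if (!any(v$data > 0)) stop("correct_bias: image has no positive intensities")
  d <- dim(v$data)
  rough <- v$data > otsu_threshold(v)
  if (!any(rough)) stop("correct_bias: empty head mask")
  h <- mm_to_voxels(radius_mm, v$spacing)
  s <- .cpp_boxsum(as.double(v$data * rough), d, h)
  n <- .cpp_boxsum(as.double(rough), d, h)
  field <- s / pmax(n, 1e-300)
  field[n <= 0] <- 0
  scale <- mean(field[rough])
  out <- v$data * (scale / pmax(field, 1e-300))
  out[field <= 0] <- v$data[field <= 0]
  vol_like(array(out, d), v)
}

#' Neck cropping and head anchor point
#'
#' Blanks slices far below the top of the head so that bright neck tissue
#' cannot disturb marker placement, and computes the anchor point `com_top`
#' used by the marker generators.  The input is Otsu-thresholded, the
#' largest 6-connected component kept, and every axial slice more than
#' `crop_extent_mm` inferior to that component's most superior slice is set
#' to zero.  `com_top` is the (intensity-unweighted) centre of mass of the
#' most superior `com_slab_mm` of the component, in physical mm in the
#' canonical frame.  No slice is blanked when the whole image lies within
#' `crop_extent_mm` of the top, so the step is a no-op on already-cropped
#' images; it is mandatory because `com_top` is needed downstream.  The
#' output grid is never resampled, only blanked, and the blanked slices are
#' reported so marker generation can fill them back into the background
#' marker.
#'
#' @param v a [vol3()] in canonical orientation (axis 3 inferior-superior).
#' @param crop_extent_mm distance below the top slice beyond which slices
#'   are blanked (180 mm for adult humans; reduce for paediatric cohorts,
#'   80 mm for macaques).
#' @param com_slab_mm thickness of the superior slab over which the centre
#'   of mass is taken (35 mm human, 15 mm macaque).
#' @return A list of class `crop_result`: `volume` (blanked `vol3`),
#'   `com_top` (mm, length 3), `blanked` (`mask3` of blanked slices),
#'   `top_mm` (superior coordinate of the head component).
#' @export
crop_neck <- function(v, crop_extent_mm = 180, com_slab_mm = 35) {
  d <- dim(v$data)
  fg <- mask_like(array(v$data > otsu_threshold(v), d), v)
  head <- cc_filter(fg, "keep_largest")
  if (!any(head$data)) stop("crop_neck: empty foreground after thresholding")
  sp3 <- v$spacing[3]
  slice_any <- apply(head$data, 3, any)
  top_k <- max(which(slice_any))
  below <- (top_k - seq_len(d[3])) * sp3
  blank_k <- below > crop_extent_mm
  out <- v$data
  if (any(blank_k)) out[, , blank_k] <- 0
  blanked <- array(FALSE, d)
  blanked[, , blank_k] <- TRUE
  slab_k <- !blank_k & below <= com_slab_mm & below >= 0 &
    seq_len(d[3]) <= top_k
  slab <- head$data
  slab[, , !slab_k] <- FALSE
  idx <- which(slab, arr.ind = TRUE)
  com_top <- index_to_mm(colMeans(idx), v$spacing)
  structure(list(volume = vol_like(out, v),
                 com_top = as.numeric(com_top),
                 blanked = mask_like(blanked, v),
                 top_mm = index_to_mm(top_k, sp3)),
            class = "crop_result")
}
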