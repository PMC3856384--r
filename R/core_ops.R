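#' Convert a physical length to voxel counts
#'
#' Lengths throughout the package are expressed in millimetres and converted
#' per axis by rounding half up, with the rule that a strictly positive
#' length never collapses to zero voxels on any axis (so an operator keeps
#' an effect on coarsely sampled axes).
#'
#' @param length_mm non-negative length in mm.
#' @param spacing per-axis voxel size in mm.
#' @return Integer vector of per-axis voxel counts.
#' @examples
#' mm_to_voxels(2, c(1, 1, 1))      # 2 2 2
#' mm_to_voxels(2, c(0.9, 0.9, 3))  # 2 2 1
#' @export
mm_to_voxels <- function(length_mm, spacing) {
  if (length(length_mm) != 1L || is.na(length_mm) || length_mm < 0)
    stop("length_mm must be a single non-negative number")
  spacing <- check_spacing(spacing)
  n <- as.integer(floor(length_mm / spacing + 0.5))
  if (length_mm > 0) n <- pmax(n, 1L)
  n
}

round_half_up <- function(x) floor(x + 0.5)

#' Structuring-element descriptions
#'
#' A `kernel_spec` names a structuring element by physical size: a sphere of
#' given radius (mm) or a box of given edge lengths (mm, per anatomical
#' axis).  Box sizes are converted to odd voxel window extents of
#' `2 * floor(round(size/spacing)/2) + 1` voxels.
#'
#' @param radius_mm sphere radius in mm (>= 0).
#' @param size_mm box edge length(s) in mm, length 1 or 3.
#' @return A `kernel_spec` object.
#' @export
kernel_sphere <- function(radius_mm) {
  if (length(radius_mm) != 1L || is.na(radius_mm) || radius_mm < 0)
    stop("sphere radius must be a single non-negative number")
  structure(list(shape = "sphere", size_mm = as.numeric(radius_mm)),
            class = "kernel_spec")
}

#' @rdname kernel_sphere
#' @export
kernel_box <- function(size_mm) {
  size_mm <- as.numeric(size_mm)
  if (length(size_mm) == 1L) size_mm <- rep(size_mm, 3L)
  if (length(size_mm) != 3L || anyNA(size_mm) || any(size_mm < 0))
    stop("box sizes must be 1 or 3 non-negative lengths in mm")
  structure(list(shape = "box", size_mm = size_mm), class = "kernel_spec")
}

# Half-widths (voxels) of the odd window implementing a box of edge size_mm.
box_halfwidth <- function(size_mm, spacing) {
  n <- pmax(1L, as.integer(round_half_up(size_mm / spacing)))
  as.integer(n %/% 2L)
}

# Voxel offsets of the metric ball of radius r mm (always includes origin).
ball_offsets <- function(radius_mm, spacing) {
  m <- ceiling(radius_mm / spacing)
  off <- as.matrix(expand.grid(x = -m[1]:m[1], y = -m[2]:m[2], z = -m[3]:m[3]))
  d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
    (off[, 3] * spacing[3])^2
  off <- off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  storage.mode(off) <- "integer"
  off
}

# Offsets of the centre plus its 6 face neighbours (the unit structuring
# element used for gradients and border extraction).
unit_offsets <- function(include_centre = TRUE) {
  off <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, -1L), c(0L, 0L, 1L))
  if (include_centre) off <- rbind(c(0L, 0L, 0L), off)
  off
}

#' Binary morphology with exact Euclidean spheres
#'
#' Erosion, dilation, opening and closing of a binary mask by the metric
#' ball of the given radius.  The ball is realised through the Euclidean
#' distance transform (thresholded at the radius), not a rasterised voxel
#' ball, so results are metric-exact on anisotropic grids: dilation keeps
#' voxels within `radius_mm` of the mask, erosion keeps voxels whose
#' distance to the complement exceeds `radius_mm`.  Boundary handling is
#' the adjoint pair: beyond-grid space counts as background for dilation
#' and as foreground for erosion, which makes the duality
#' `dilate(m) == !erode(!m)` exact and the opening and closing idempotent.
#'
#' @param m a [mask3()].
#' @param op one of `"erode"`, `"dilate"`, `"open"`, `"close"`.
#' @param radius_mm ball radius in mm; 0 is the identity.
#' @return A `mask3` on the same grid.
#' @export
binary_morph <- function(m, op = c("erode", "dilate", "open", "close"),
                         radius_mm) {
  op <- match.arg(op)
  if (length(radius_mm) != 1L || is.na(radius_mm) || radius_mm < 0)
    stop("radius_mm must be a single non-negative number")
  if (radius_mm == 0) return(m)
  switch(op,
    erode = bm_erode(m, radius_mm),
    dilate = bm_dilate(m, radius_mm),
    open = bm_dilate(bm_erode(m, radius_mm), radius_mm),
    close = bm_erode(bm_dilate(m, radius_mm), radius_mm))
}

bm_dilate <- function(m, r) {
  d <- dim(m$data)
  d2 <- .cpp_sq_edt(as.logical(m$data), d, m$spacing)
  mask_like(array(d2 <= r * r, d), m)
}

bm_erode <- function(m, r) {
  d <- dim(m$data)
  d2 <- .cpp_sq_edt(as.logical(!m$data), d, m$spacing)
  mask_like(m$data & array(d2 > r * r, d), m)
}

#' Grayscale morphology
#'
#' Moving minimum/maximum (and their compositions) of a volume over a
#' structuring element given as a [kernel_spec][kernel_sphere]: boxes run as
#' separable sliding-window filters, spheres as explicit metric-ball
#' footprints.  Windows are truncated at the grid border (outside voxels
#' ignored), which preserves the adjunction and hence idempotence of the
#' opening and closing.
#'
#' @param v a [vol3()].
#' @param op one of `"erode"`, `"dilate"`, `"open"`, `"close"`.
#' @param kernel a `kernel_spec`.
#' @return A `vol3` on the same grid.
#' @export
gray_morph <- function(v, op = c("erode", "dilate", "open", "close"), kernel) {
  op <- match.arg(op)
  if (!inherits(kernel, "kernel_spec")) stop("kernel must be a kernel_spec")
  switch(op,
    erode = gm_apply(v, kernel, FALSE),
    dilate = gm_apply(v, kernel, TRUE),
    open = gm_apply(gm_apply(v, kernel, FALSE), kernel, TRUE),
    close = gm_apply(gm_apply(v, kernel, TRUE), kernel, FALSE))
}

gm_apply <- function(v, kernel, do_max) {
  d <- dim(v$data)
  out <- if (kernel$shape == "box") {
    h <- box_halfwidth(kernel$size_mm, v$spacing)
    .cpp_box_minmax(as.double(v$data), d, h, do_max)
  } else {
    off <- ball_offsets(kernel$size_mm, v$spacing)
    .cpp_footprint_minmax(as.double(v$data), d, off, do_max, NULL)
  }
  vol_like(array(out, d), v)
}

#' Box mean filter
#'
#' Mean over a cubic window of the given radius (mm per side from the
#' centre, ITK box-radius convention).  At the image border the window is
#' truncated and the mean taken over the in-bounds voxels only.
#'
#' @param v a [vol3()].
#' @param radius_mm box radius in mm (> 0).
#' @return A `vol3` of local means.
#' @export
box_mean <- function(v, radius_mm) {
  if (length(radius_mm) != 1L || is.na(radius_mm) || radius_mm <= 0)
    stop("radius_mm must be a single positive number")
  d <- dim(v$data)
  h <- mm_to_voxels(radius_mm, v$spacing)
  s <- .cpp_boxsum(as.double(v$data), d, h)
  n <- .cpp_boxsum(rep(1.0, prod(d)), d, h)
  vol_like(array(s / n, d), v)
}

#' Masked mean filter
#'
#' Mean over a box window ignoring voxels outside the mask.  Where the
#' window contains no in-mask voxel the output is 0 (such voxels lie far
#' from any region the pipelines later read).
#'
#' @param v a [vol3()].
#' @param m a [mask3()] on the same grid.
#' @param kernel a box [kernel_spec][kernel_box] giving the full window edge
#'   lengths in mm.
#' @return A `vol3` of in-mask local means.
#' @export
masked_mean <- function(v, m, kernel) {
  stopifnot_same_grid(v, m)
  if (!inherits(kernel, "kernel_spec") || kernel$shape != "box")
    stop("masked_mean requires a box kernel_spec")
  d <- dim(v$data)
  h <- box_halfwidth(kernel$size_mm, v$spacing)
  s <- .cpp_boxsum(as.double(v$data * m$data), d, h)
  n <- .cpp_boxsum(as.double(m$data), d, h)
  out <- s / pmax(n, 1e-300)
  out[n <= 0] <- 0
  vol_like(array(out, d), v)
}

#' Otsu threshold within a region
#'
#' Threshold maximising the between-class variance of a fixed-bin histogram
#' (128 bins over the region's value range).  Returns the bin edge between
#' the two classes; values at or below the threshold are "dark", values
#' above are "bright".  Deterministic; ties resolve to the lowest edge.
#'
#' @param v a [vol3()].
#' @param region optional [mask3()] restricting the histogram; default whole
#'   image.
#' @param bins histogram bin count.
#' @return The threshold intensity (scalar).
#' @export
otsu_threshold <- function(v, region = NULL, bins = 128L) {
  vals <- if (is.null(region)) as.vector(v$data) else {
    stopifnot_same_grid(v, region)
    v$data[region$data]
  }
  if (length(vals) == 0L) stop("otsu_threshold: empty region")
  lo <- min(vals); hi <- max(vals)
  if (lo == hi)
    stop("otsu_threshold: region is constant (degenerate histogram)")
  breaks <- seq(lo, hi, length.out = bins + 1L)
  bi <- findInterval(vals, breaks, all.inside = TRUE)
  cnt <- as.numeric(tabulate(bi, nbins = bins))
  mid <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  w <- cumsum(cnt)
  s <- cumsum(cnt * mid)
  n <- w[bins]; tot <- s[bins]
  k <- seq_len(bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, bins - 1L)
  mu0 <- s[k][valid] / w0[valid]
  mu1 <- (tot - s[k][valid]) / w1[valid]
  bc[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  breaks[which.max(bc) + 1L]
}

#' Quantile of in-mask intensities (nearest-rank)
#'
#' Order statistic of the values inside a region using the nearest-rank
#' definition: the `ceil(q * n)`-th smallest value (at least the first).
#' `q = 0` gives the minimum, `q = 1` the maximum.
#'
#' @param v a [vol3()].
#' @param region a [mask3()]; must be nonempty.  `NULL` uses the whole grid.
#' @param q fraction in \[0, 1\].
#' @return The order-statistic intensity.
#' @export
quantile_in_mask <- function(v, region = NULL, q) {
  if (length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be a single fraction in [0, 1]")
  vals <- if (is.null(region)) as.vector(v$data) else {
    stopifnot_same_grid(v, region)
    v$data[region$data]
  }
  n <- length(vals)
  if (n == 0L) stop("quantile_in_mask: empty region")
  r <- max(1L, as.integer(ceiling(q * n)))
  sort(vals, partial = r)[r]
}

#' Filter connected components of a mask
#'
#' 6-connected component filtering: keep the largest component (ties go to
#' the component first met in scan order), drop components whose physical
#' volume is below a cutoff (`voxels * voxel volume < min_mm3`), or keep the
#' components overlapping a reference mask by at least one voxel.
#'
#' @param m a [mask3()].
#' @param mode `"keep_largest"`, `"min_volume"` or `"keep_touching"`.
#' @param min_mm3 volume cutoff in mm^3 (for `"min_volume"`).
#' @param touching reference [mask3()] (for `"keep_touching"`).
#' @return A `mask3` that is a subset of `m`; an empty input passes through.
#' @export
cc_filter <- function(m, mode = c("keep_largest", "min_volume",
                                  "keep_touching"),
                      min_mm3 = NULL, touching = NULL) {
  mode <- match.arg(mode)
  d <- dim(m$data)
  lab <- array(.cpp_label6(as.logical(m$data), d), d)
  nlab <- max(lab)
  if (nlab == 0L)
    return(mask_like(array(FALSE, d), m))
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- switch(mode,
    keep_largest = which.max(sizes),
    min_volume = {
      if (is.null(min_mm3)) stop("min_volume mode needs min_mm3")
      which(sizes * prod(m$spacing) >= min_mm3)
    },
    keep_touching = {
      if (is.null(touching)) stop("keep_touching mode needs a reference mask")
      stopifnot_same_grid(m, touching)
      unique(lab[touching$data & lab > 0L])
    })
  mask_like(array(lab %in% keep & lab > 0L, d), m)
}

#' Smoothed morphological gradient
#'
#' Morphological gradient (unit dilation minus unit erosion over the centre
#' plus its six face neighbours), optionally restricted to a mask --
#' out-of-mask voxels are treated as absent so no spurious edge appears at
#' the mask border, and out-of-mask output is 0 -- followed by Gaussian
#' smoothing with standard deviation `sigma_mm`.
#'
#' @param v a [vol3()].
#' @param sigma_mm Gaussian standard deviation in mm (> 0).
#' @param within optional [mask3()] restricting the gradient support.
#' @return A non-negative `vol3`.
#' @export
gradient_smooth <- function(v, sigma_mm, within = NULL) {
  if (length(sigma_mm) != 1L || is.na(sigma_mm) || sigma_mm <= 0)
    stop("sigma_mm must be a single positive number")
  d <- dim(v$data)
  off <- unit_offsets()
  maskarg <- NULL
  if (!is.null(within)) {
    stopifnot_same_grid(v, within)
    maskarg <- as.logical(within$data)
  }
  dat <- as.double(v$data)
  dil <- .cpp_footprint_minmax(dat, d, off, TRUE, maskarg)
  ero <- .cpp_footprint_minmax(dat, d, off, FALSE, maskarg)
  g <- dil - ero
  sm <- .cpp_gauss(g, d, sigma_mm / v$spacing)
  vol_like(array(pmax(sm, 0), d), v)
}

#' Watershed transform from markers
#'
#' Priority-flood of a control surface from labelled seed regions: a global
#' queue ordered by control value (FIFO within equal values) grows each
#' marker's region until every voxel is claimed.  Regions touch -- no
#' watershed-line voxels are produced -- so exactly one region per marker
#' label results, each guaranteed to contain its marker.  Connectivity is 6;
#' the combination of stable queue and fixed scan order makes the result
#' fully deterministic, including on plateaus.
#'
#' @param control a [vol3()]; ridges of this surface become region
#'   boundaries.
#' @param markers a [merge_markers()] result, or any integer label array
#'   (`markers3` or plain array) with 0 = unassigned and positive seeds.
#' @return A `markers3` label image with every voxel assigned a positive
#'   label; marker voxels keep their input labels.
#' @export
watershed_markers <- function(control, markers) {
  d <- dim(control$data)
  if (inherits(markers, "markers3")) {
    stopifnot_same_grid(control, markers)
    lab <- markers$data
    present <- sort(unique(lab[lab > 0L]))
    if (!all(c(1L, 2L) %in% present))
      stop("marker image must contain at least one voxel of labels 1 and 2")
  } else {
    lab <- markers
    if (!identical(dim(lab), d)) stop("marker array shape mismatch")
  }
  storage.mode(lab) <- "integer"
  if (any(lab < 0L, na.rm = TRUE) || anyNA(lab))
    stop("marker labels must be non-negative integers")
  out <- .cpp_watershed(as.double(control$data), lab, d)
  structure(list(data = array(out, d), spacing = control$spacing,
                 affine = control$affine, io = control$io),
            class = "markers3")
}

#' Impose regional minima by reconstruction (reference implementation)
#'
#' Forces the control surface to have regional minima only at the marker
#' components: marker voxels are driven to below the global minimum and the
#' surface is rebuilt by reconstruction by erosion (iterated conditional
#' unit erosions).  This is the classical topology transformation that,
#' followed by an unseeded flood, reproduces the watershed transform from
#' markers; in this package it serves as the independent cross-check for
#' [watershed_markers()] and is far too slow for production volumes.
#'
#' @param control a [vol3()].
#' @param markers a nonempty [mask3()] of marker voxels.
#' @return A `vol3` whose regional minima all intersect `markers`.
#' @export
impose_minima <- function(control, markers) {
  stopifnot_same_grid(control, markers)
  if (!any(markers$data)) stop("impose_minima: empty marker mask")
  d <- dim(control$data)
  rng <- range(control$data)
  lo <- rng[1] - max(rng[2] - rng[1], 1) * 0.1
  hi <- rng[2]
  seed <- ifelse(markers$data, lo, hi)
  maskimg <- ifelse(markers$data, lo, control$data)
  out <- .cpp_reconstruct_erosion(as.double(seed), as.double(maskimg), d)
  vol_like(array(out, d), control)
}

#' Regional minima of a volume
#'
#' Connected plateaus (6-connectivity, exactly equal values) none of whose
#' voxels has a strictly lower face neighbour.  Used for QC and for testing
#' minima imposition.
#'
#' @param v a [vol3()].
#' @return A `mask3` marking all regional-minimum voxels.
#' @export
regional_minima <- function(v) {
  d <- dim(v$data)
  nb_min <- .cpp_footprint_minmax(as.double(v$data), d,
                                  unit_offsets(include_centre = FALSE),
                                  FALSE, NULL)
  has_lower <- array(nb_min < as.double(v$data), d)
  out <- array(FALSE, d)
  for (val in unique(v$data[!has_lower])) {
    plate <- array(v$data == val, d)
    lab <- array(.cpp_label6(plate, d), d)
    bad <- unique(lab[plate & has_lower])
    out <- out | (plate & !(lab %in% bad))
  }
  mask_like(out, v)
}
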