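#' Parameters of the human extraction pipeline
#'
#' All sizes are physical (mm, mm^3) and apply regardless of voxel spacing.
#' The defaults are the values the pipeline was designed with; individual
#' fields can be overridden (e.g. `bg_dilate_mm` is the knob to reduce for
#' intra-surgical scans with open skulls, and `crop_extent_mm` can be
#' reduced for paediatric cohorts).
#'
#' @param box_edge_mm edge length of the seed box placed below `com_top`.
#' @param box_below_com_mm distance of the seed-box centre below `com_top`.
#' @param bright_ratio upper band factor for the brain marker
#'   (`median .. bright_ratio * median`) and bright-marker threshold factor.
#' @param open_brain_mm opening radius applied to the brain-marker band.
#' @param bg_erode_mm erosion of the inverted brain marker (step 1).
#' @param bg_open_mm opening that smooths the background marker (step 2).
#' @param gs_open_box_mm grayscale opening box edge before Otsu (step 3).
#' @param bg_erode2_mm background erosion before component selection
#'   (step 6).
#' @param bg_dilate_mm background re-dilation, slightly larger than
#'   `bg_erode2_mm` so the marker overlaps the scalp (step 7).
#' @param border_zone_mm thickness of the Stage-2 border zone.
#' @param dark_erode_mm small grayscale erosion removing fine dural
#'   structure before the dark-marker search.
#' @param local_mean_box_mm masked-mean window edge for local brightness.
#' @param dark_fraction voxels below this fraction of local brightness are
#'   dark-marker candidates.
#' @param bz2_erode_mm erosion for the thinner bright-marker border zone.
#' @param sup_zone_mm height above the Stage-1 bounding-box floor defining
#'   the superior zone searched for bright (marrow) markers.
#' @param min_cc_mm3 minimum volume of border-zone marker components.
#' @param final_dilate_mm Stage-2 re-dilation compensating `dark_erode_mm`.
#' @param smooth_open_mm,smooth_close_mm mask smoothing radii.
#' @param grad_sigma_mm Gaussian sigma of the smoothed gradient control.
#' @param crop_extent_mm,com_slab_mm neck-crop geometry (see [crop_neck()]).
#' @param bias_radius_mm box radius of the optional bias correction.
#' @return A `human_params` list.
#' @export
human_params <- function(box_edge_mm = 40, box_below_com_mm = 50,
                         bright_ratio = 1.25, open_brain_mm = 2,
                         bg_erode_mm = 10, bg_open_mm = 30,
                         gs_open_box_mm = 5, bg_erode2_mm = 5,
                         bg_dilate_mm = 6, border_zone_mm = 10,
                         dark_erode_mm = 1, local_mean_box_mm = 30,
                         dark_fraction = 0.6, bz2_erode_mm = 3.3,
                         sup_zone_mm = 90, min_cc_mm3 = 10,
                         final_dilate_mm = 1, smooth_open_mm = 5,
                         smooth_close_mm = 6.5, grad_sigma_mm = 1,
                         crop_extent_mm = 180, com_slab_mm = 35,
                         bias_radius_mm = 30) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) stop("all parameters must be >= 0")
  if (p$bright_ratio <= 1) stop("bright_ratio must exceed 1")
  if (p$dark_fraction <= 0 || p$dark_fraction >= 1)
    stop("dark_fraction must lie in (0, 1)")
  structure(p, class = "human_params")
}

# Axis-aligned box mask: centre and edge sizes in physical mm (canonical
# frame), clipped to the grid.
box_mask <- function(centre_mm, size_mm, like) {
  d <- dim(like$data)
  out <- array(FALSE, d)
  lo <- ceiling(mm_to_index(centre_mm - size_mm / 2, like$spacing) - 1e-6)
  hi <- floor(mm_to_index(centre_mm + size_mm / 2, like$spacing) + 1e-6)
  lo <- pmax(lo, 1)
  hi <- pmin(hi, d)
  if (any(lo > hi)) return(mask_like(out, like))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mask_like(out, like)
}

trace_put <- function(trace, name, value) {
  if (!is.null(trace)) assign(name, value, envir = trace)
  invisible(NULL)
}

#' Stage-1 brain marker (human)
#'
#' Places a seed box 50 mm below `com_top`, takes the box's median T1
#' intensity, masks voxels in the band `[median, bright_ratio * median]`,
#' opens by a 2 mm sphere and keeps the components touching the box.  The
#' result must fall entirely within the brain; the box geometry and the
#' tight intensity band around white matter are what guarantee this on
#' well-formed heads.
#'
#' @param R0 neck-cropped T1 [vol3()].
#' @param com_top anchor point in mm from [crop_neck()].
#' @param params a [human_params()] list.
#' @param trace optional environment collecting intermediates.
#' @return A `mask3` brain marker (`M_A`).
#' @export
stage1_brain_marker <- function(R0, com_top, params = human_params(),
                                trace = NULL) {
  box <- box_mask(com_top - c(0, 0, params$box_below_com_mm),
                  rep(params$box_edge_mm, 3), R0)
  if (!any(box$data)) stop("seed box does not intersect the image")
  t1_med <- quantile_in_mask(R0, box, 0.5)
  band <- mask_like(R0$data >= t1_med &
                      R0$data <= params$bright_ratio * t1_med, R0)
  opened <- binary_morph(band, "open", params$open_brain_mm)
  ma <- cc_filter(opened, "keep_touching", touching = box)
  if (!any(ma$data)) stop("stage-1 brain marker not found")
  trace_put(trace, "seed_box", box)
  trace_put(trace, "T1_med", t1_med)
  trace_put(trace, "M_A", ma)
  ma
}

#' Stage-1 background marker (human)
#'
#' Builds the non-brain marker by aggressive large-kernel morphology: the
#' inverted brain marker is eroded by a 10 mm sphere, smoothed by a 30 mm
#' opening (largest component kept), bright voxels -- identified by an Otsu
#' threshold of the 5 mm box-opened T1 inside the current marker -- are
#' removed, and the remainder is eroded 5 mm, reduced to its largest
#' component and re-dilated 6 mm so that it overlaps the scalp by a small
#' margin.  Slices blanked by neck cropping are finally filled in.  The
#' result must fall entirely outside the brain.
#'
#' @param R0 neck-cropped T1 [vol3()].
#' @param M_A brain marker from [stage1_brain_marker()].
#' @param blanked `mask3` of blanked slices from [crop_neck()].
#' @inheritParams stage1_brain_marker
#' @return A `mask3` background marker (`N_F`), disjoint from `M_A`.
#' @export
stage1_background_marker <- function(R0, M_A, blanked,
                                     params = human_params(), trace = NULL) {
  na_ <- binary_morph(mask_like(!M_A$data, M_A), "erode", params$bg_erode_mm)
  nb <- cc_filter(binary_morph(na_, "open", params$bg_open_mm),
                  "keep_largest")
  ra <- gray_morph(R0, "open", kernel_box(params$gs_open_box_mm))
  th <- otsu_threshold(ra, region = nb)
  nc <- mask_like(nb$data & !(ra$data > th), nb)
  nd <- cc_filter(binary_morph(nc, "erode", params$bg_erode2_mm),
                  "keep_largest")
  if (!any(nd$data))
    stop("background marker vanished after erosion")
  ne <- binary_morph(nd, "dilate", params$bg_dilate_mm)
  nf <- mask_like(ne$data | blanked$data, ne)
  if (any(nf$data & M_A$data))
    stop("background marker overlaps the brain marker")
  for (nm in c("N_A", "N_B", "R_A1", "N_C", "N_D", "N_E", "N_F"))
    trace_put(trace, nm, switch(nm, N_A = na_, N_B = nb, R_A1 = ra, N_C = nc,
                                N_D = nd, N_E = ne, N_F = nf))
  nf
}

#' Stage-1 segmentation by flooding the inverted T1
#'
#' Runs the watershed transform from markers on the inverted T1 (max(R0) -
#' R0, so dark bone/CSF between brain and scalp becomes the separating
#' ridge).  The brain mask is the label-1 region; it is intended to be
#' conservative -- all brain tissue, some non-brain allowed.
#'
#' @param R0 neck-cropped T1 [vol3()].
#' @param MN1 marker image from [merge_markers()].
#' @param trace optional environment collecting intermediates.
#' @return A `mask3` (`B_1`).
#' @export
stage1_segment <- function(R0, MN1, trace = NULL) {
  ctrl <- vol_like(max(R0$data) - R0$data, R0)
  ws <- watershed_markers(ctrl, MN1)
  b1 <- mask_like(ws$data == 1L, R0)
  trace_put(trace, "inv_control", ctrl)
  trace_put(trace, "ws1", ws)
  trace_put(trace, "B_1", b1)
  b1
}

#' Stage-2 marker generation (human)
#'
#' Refinement markers near the Stage-1 boundary: a core brain marker
#' (voxels at or above the in-mask median, at least 10 mm inside the
#' boundary), dark markers (below 60 % of the masked local mean brightness,
#' within the 10 mm border zone, after a 1 mm grayscale erosion removing
#' fine dural structure), and bright markers for cancellous bone (above
#' 1.25 x the core-marker median, within a 3.3 mm border zone, in the
#' superior zone 90 mm or more above the eroded mask's bounding-box floor).
#' Dark and bright markers are merged, components under 10 mm^3 dropped,
#' and the result merged with the Stage-1 background region.
#'
#' @param R0 neck-cropped T1 [vol3()].
#' @param B1 Stage-1 brain mask.
#' @inheritParams stage1_brain_marker
#' @return A list: `MN2` (marker image), `N_bright` (for the final removal
#'   step), `M_2`, `N_2`, `N_dark`, `R_B` (eroded, masked T1 reused by the
#'   control image), `t50`.
#' @export
stage2_markers <- function(R0, B1, params = human_params(), trace = NULL) {
  if (!any(B1$data)) stop("empty Stage-1 mask")
  t50 <- quantile_in_mask(R0, B1, 0.5)
  b1e <- binary_morph(B1, "erode", params$border_zone_mm)
  bz1 <- mask_like(B1$data & !b1e$data, B1)
  m2 <- mask_like(R0$data >= t50 & b1e$data, B1)
  if (!any(m2$data)) stop("empty Stage-2 brain marker")

  re1 <- gray_morph(R0, "erode", kernel_sphere(params$dark_erode_mm))
  rb <- vol_like(re1$data * B1$data, R0)
  rlb <- masked_mean(R0, B1, kernel_box(params$local_mean_box_mm))
  radj <- rb$data / pmax(rlb$data, 1e-300)
  radj[rlb$data <= 0] <- 0
  ndark <- mask_like(radj < params$dark_fraction & bz1$data, B1)

  t50b <- quantile_in_mask(R0, m2, 0.5)
  b2e <- binary_morph(B1, "erode", params$bz2_erode_mm)
  bz2 <- mask_like(B1$data & !b2e$data, B1)
  bsup <- array(FALSE, dim(B1$data))
  if (any(b1e$data)) {
    ks <- which(apply(b1e$data, 3, any))
    zmm <- (seq_len(dim(B1$data)[3]) - min(ks)) * B1$spacing[3]
    bsup[, , zmm >= params$sup_zone_mm] <- TRUE
  }
  nbright <- mask_like(R0$data > params$bright_ratio * t50b &
                         bz2$data & bsup, B1)

  nbz <- cc_filter(mask_like(ndark$data | nbright$data, B1), "min_volume",
                   min_mm3 = params$min_cc_mm3)
  n2 <- mask_like(!B1$data | nbz$data, B1)
  mn2 <- merge_markers(m2, n2)
  for (nm in c("B_1e", "B_bz1", "M_2", "R_B", "R_lb", "N_dark", "B_bz2",
               "B_sup", "N_bright", "N_bz", "N_2", "MN_2"))
    trace_put(trace, nm, switch(nm, B_1e = b1e, B_bz1 = bz1, M_2 = m2,
                                R_B = rb, R_lb = rlb, N_dark = ndark,
                                B_bz2 = bz2, B_sup = mask_like(bsup, B1),
                                N_bright = nbright, N_bz = nbz, N_2 = n2,
                                MN_2 = mn2))
  list(MN2 = mn2, N_bright = nbright, M_2 = m2, N_2 = n2, N_dark = ndark,
       R_B = rb, t50 = t50)
}

#' Stage-2 control surface
#'
#' Combines raw T1 values with the T1 gradient so that boundaries already
#' correct after Stage 1 are retained while gradient ridges refine the
#' rest: intensities above `t50` are clipped to `t50` (weakening the
#' white/gray transition), the Stage-1 boundary voxels get their bright
#' excess over the boundary median (clipped at zero), a masked
#' morphological gradient smoothed by a 1 mm Gaussian is added, and the
#' voxel-wise maximum of the two terms is the control.
#'
#' @param R_B eroded (or raw, for the macaque variant), Stage-1-masked T1.
#' @param B1 Stage-1 brain mask.
#' @param t50 median T1 intensity within `B1`.
#' @inheritParams stage1_brain_marker
#' @return A non-negative `vol3` (`R_2`).
#' @export
stage2_control <- function(R_B, B1, t50, params = human_params(),
                           trace = NULL) {
  d <- dim(R_B$data)
  rc <- pmin(R_B$data, t50)
  ero <- .cpp_footprint_minmax(as.double(B1$data), d, unit_offsets(), FALSE,
                               NULL)
  border <- B1$data & !(array(ero, d) > 0.5)
  rd <- array(0, d)
  if (any(border)) {
    vals <- rc[border]
    med <- sort(vals, partial = ceiling(length(vals) / 2))[
      ceiling(length(vals) / 2)]
    rd[border] <- pmax(rc[border] - med, 0)
  }
  re <- gradient_smooth(vol_like(rc, R_B), params$grad_sigma_mm, within = B1)
  r2 <- vol_like(pmax(rd, re$data), R_B)
  trace_put(trace, "R_C", vol_like(rc, R_B))
  trace_put(trace, "R_D", vol_like(rd, R_B))
  trace_put(trace, "R_E", re)
  trace_put(trace, "R_2", r2)
  r2
}

#' Stage-2 segmentation
#'
#' Floods the Stage-2 control surface from the refined markers, dilates the
#' brain region by `final_dilate_mm` (compensating the grayscale erosion
#' applied in the dark-marker branch) and removes any bright-marker voxels
#' the dilation may have re-included.
#'
#' @param R2 control surface from [stage2_control()].
#' @param MN2 marker image from [stage2_markers()].
#' @param N_bright bright-marker mask to subtract.
#' @param final_dilate_mm re-dilation radius (0 disables, as in the macaque
#'   pipeline where the control was not eroded).
#' @param trace optional environment collecting intermediates.
#' @return A `mask3` Stage-2 brain mask.
#' @export
stage2_segment <- function(R2, MN2, N_bright, final_dilate_mm = 1,
                           trace = NULL) {
  ws <- watershed_markers(R2, MN2)
  raw <- mask_like(ws$data == 1L, R2)
  out <- if (final_dilate_mm > 0)
    binary_morph(raw, "dilate", final_dilate_mm) else raw
  out <- mask_like(out$data & !N_bright$data, out)
  trace_put(trace, "ws2", ws)
  trace_put(trace, "B_2raw", raw)
  trace_put(trace, "B_2", out)
  out
}

#' Morphological mask smoothing
#'
#' Stage 1 masks are smoothed by an opening (radius `smooth_open_mm`)
#' followed by a closing (radius `smooth_close_mm`); Stage 2 masks by the
#' closing only.  Both compositions are idempotent.
#'
#' @param m a [mask3()].
#' @param stage 1 or 2.
#' @param params a [human_params()] list (radii are shared by both
#'   pipelines).
#' @return A smoothed `mask3`.
#' @export
smooth_mask <- function(m, stage = 2, params = human_params()) {
  if (stage == 1)
    m <- binary_morph(m, "open", params$smooth_open_mm)
  binary_morph(m, "close", params$smooth_close_mm)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Extract a human brain
#'
#' Runs the complete two-stage pipeline: optional bias correction, neck
#' cropping, Stage-1 marker generation and watershed on the inverted T1,
#' Stage-2 marker refinement and watershed on the gradient-derived control,
#' and morphological mask smoothing.  The pipeline is fully deterministic.
#' Any failure is reported with the name of the stage that produced it, so
#' parameter tuning can be targeted at the step that failed.
#'
#' @param v a [vol3()] T1 head volume in canonical orientation (use
#'   [read_volume()] for files).
#' @param params a [human_params()] list.
#' @param bias_correct apply [correct_bias()] first (optional step).
#' @param smooth also return smoothed masks.
#' @param stages run stage 1 only, or both stages.
#' @param keep_trace collect every intermediate image in `$trace`.
#' @return A list of class `scalp_result`: `stage1_mask`, `stage2_mask`,
#'   `stage1_smoothed`, `stage2_smoothed` (NULL where not computed),
#'   `com_top` and `trace` (named by the conventional symbols of the
#'   intermediate images).
#' @export
extract_brain_human <- function(v, params = human_params(),
                                bias_correct = FALSE, smooth = TRUE,
                                stages = 2, keep_trace = FALSE) {
  trace <- if (keep_trace) new.env(parent = emptyenv()) else NULL
  if (bias_correct)
    v <- with_stage("bias correction", correct_bias(v, params$bias_radius_mm))
  cr <- with_stage("neck crop",
                   crop_neck(v, params$crop_extent_mm, params$com_slab_mm))
  r0 <- cr$volume
  trace_put(trace, "R_0", r0)
  ma <- with_stage("stage-1 brain marker",
                   stage1_brain_marker(r0, cr$com_top, params, trace))
  nf <- with_stage("stage-1 background marker",
                   stage1_background_marker(r0, ma, cr$blanked, params,
                                            trace))
  mn1 <- with_stage("stage-1 marker merge", merge_markers(ma, nf))
  trace_put(trace, "MN_1", mn1)
  b1 <- with_stage("stage-1 watershed", stage1_segment(r0, mn1, trace))
  s1s <- if (smooth) smooth_mask(b1, 1, params) else NULL
  if (stages < 2) {
    return(structure(list(stage1_mask = b1, stage2_mask = NULL,
                          stage1_smoothed = s1s, stage2_smoothed = NULL,
                          com_top = cr$com_top,
                          trace = trace_list(trace), params = params),
                     class = "scalp_result"))
  }
  mk <- with_stage("stage-2 markers", stage2_markers(r0, b1, params, trace))
  r2 <- with_stage("stage-2 control",
                   stage2_control(mk$R_B, b1, mk$t50, params, trace))
  b2 <- with_stage("stage-2 watershed",
                   stage2_segment(r2, mk$MN2, mk$N_bright,
                                  params$final_dilate_mm, trace))
  s2s <- if (smooth) smooth_mask(b2, 2, params) else NULL
  structure(list(stage1_mask = b1, stage2_mask = b2, stage1_smoothed = s1s,
                 stage2_smoothed = s2s, com_top = cr$com_top,
                 trace = trace_list(trace), params = params),
            class = "scalp_result")
}

trace_list <- function(trace) {
  if (is.null(trace)) return(NULL)
  as.list(trace)
}

#' @export
print.scalp_result <- function(x, ...) {
  cat("<scalp_result>\n")
  for (nm in c("stage1_mask", "stage2_mask", "stage1_smoothed",
               "stage2_smoothed")) {
    m <- x[[nm]]
    if (!is.null(m))
      cat(sprintf("  %-16s %d voxels (%.1f cm^3)\n", nm, sum(m$data),
                  sum(m$data) * prod(m$spacing) / 1000))
  }
  invisible(x)
}
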