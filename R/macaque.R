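#' Parameters of the macaque extraction pipeline
#'
#' The macaque variant encodes approximate brain size directly through box
#' geometry rather than through filter sizes, because macaque skull muscles
#' are similar in scale to the brain and defeat purely kernel-based
#' selection.  All sizes are physical mm; boxes are given per anatomical
#' axis (left-right, anterior-posterior, superior-inferior).
#'
#' @param crop_extent_mm neck-crop distance below the top of the skull.
#' @param com_slab_mm superior slab thickness for the `com_top` anchor.
#' @param brainbox_mm box blanked out of the background marker (the rough
#'   brain bounding volume), LR x AP x SI.
#' @param box_below_com_mm distance of the box centres below `com_top`.
#' @param close_box_mm grayscale closing box edge removing narrow dark
#'   spaces (brain-scalp gap) while keeping large ones (eyes).
#' @param bg_quantile_lo quantile of the closed image defining
#'   above-background intensity.
#' @param bg_quantile quantile of above-background voxels thresholding dark
#'   regions.
#' @param anterior_limit_mm markers from dark components are kept only
#'   anterior of `com_top` plus this distance (eye region).
#' @param min_cc_mm3 minimum dark-component volume.
#' @param cc_dilate_mm dilation of surviving dark components.
#' @param brain_seed_box_mm brain seed box, LR x AP x SI.
#' @param stage2_erode_mm erosion of the Stage-1 brain region for the
#'   Stage-2 core marker.
#' @param grad_sigma_mm Gaussian sigma of the gradient control.
#' @param smooth_open_mm,smooth_close_mm optional mask-smoothing radii.
#' @param bias_radius_mm box radius of the bias correction.
#' @return A `macaque_params` list.
#' @export
macaque_params <- function(crop_extent_mm = 80, com_slab_mm = 15,
                           brainbox_mm = c(70, 90, 65),
                           box_below_com_mm = 35, close_box_mm = 8,
                           bg_quantile_lo = 0.01, bg_quantile = 0.25,
                           anterior_limit_mm = 20, min_cc_mm3 = 100,
                           cc_dilate_mm = 3,
                           brain_seed_box_mm = c(10, 10, 15),
                           stage2_erode_mm = 5, grad_sigma_mm = 1,
                           smooth_open_mm = 5, smooth_close_mm = 6.5,
                           bias_radius_mm = 30) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) stop("all parameters must be >= 0")
  if (p$bg_quantile_lo <= 0 || p$bg_quantile_lo >= 1 ||
      p$bg_quantile <= 0 || p$bg_quantile >= 1)
    stop("quantiles must lie in (0, 1)")
  structure(p, class = "macaque_params")
}

#' Stage-1 markers for macaque scans
#'
#' The background marker starts as the entire image (label 2), from which a
#' brain-sized box centred `box_below_com_mm` below `com_top` is blanked.
#' Markers for large dark anterior structures (eyes) are then added: a
#' grayscale box closing removes narrow dark spaces such as the brain-scalp
#' gap, dark voxels are selected by quantile thresholds (below the
#' `bg_quantile` of above-background voxels, or below background
#' altogether), the selection is restricted to the region anterior of
#' `com_top` + `anterior_limit_mm`, components under `min_cc_mm3` are
#' dropped and the survivors dilated.  The brain marker is a small box
#' (label 1) at the same centre, overwriting anything beneath it.
#'
#' @param R0 neck-cropped (bias-corrected) T1 [vol3()].
#' @param com_top anchor from [crop_neck()].
#' @param params a [macaque_params()] list.
#' @param trace optional environment collecting intermediates.
#' @return A list: `MN1` (marker image) and `R_A` (closed image, reused by
#'   the Stage-2 marker).
#' @export
macaque_stage1_markers <- function(R0, com_top, params = macaque_params(),
                                   trace = NULL) {
  d <- dim(R0$data)
  centre <- com_top - c(0, 0, params$box_below_com_mm)
  bigbox <- box_mask(centre, params$brainbox_mm, R0)
  nb <- mask_like(!bigbox$data, R0)   # N_A is all-TRUE; blanking yields N_B
  ra <- gray_morph(R0, "close", kernel_box(params$close_box_mm))
  q1 <- quantile_in_mask(ra, NULL, params$bg_quantile_lo)
  ba <- mask_like(ra$data > q1, R0)
  q25 <- quantile_in_mask(ra, ba, params$bg_quantile)
  bb <- mask_like(ra$data < q25, R0)
  bc <- mask_like(bb$data | !ba$data, R0)
  # Blank everything posterior of com_top + anterior_limit (axis 2 runs
  # posterior -> anterior in the canonical frame).
  jcut <- mm_to_index(com_top[2] + params$anterior_limit_mm, R0$spacing[2])
  post <- seq_len(d[2]) <= jcut
  bcd <- bc$data
  bcd[, post, ] <- FALSE
  bc <- mask_like(bcd, R0)
  bd <- binary_morph(cc_filter(bc, "min_volume", min_mm3 = params$min_cc_mm3),
                     "dilate", params$cc_dilate_mm)
  ncm <- mask_like(nb$data | bd$data, R0)
  seed <- box_mask(centre, params$brain_seed_box_mm, R0)
  if (!any(seed$data)) stop("brain seed box lies outside the image")
  lab <- array(0L, d)
  lab[ncm$data] <- 2L
  lab[seed$data] <- 1L
  mn1 <- structure(list(data = lab, spacing = R0$spacing, affine = R0$affine,
                        io = R0$io), class = "markers3")
  for (nm in c("N_B", "R_A", "B_A", "B_B", "B_C", "B_D", "N_C", "seed_box",
               "MN_1"))
    trace_put(trace, nm, switch(nm, N_B = nb, R_A = ra, B_A = ba, B_B = bb,
                                B_C = bc, B_D = bd, N_C = ncm,
                                seed_box = seed, MN_1 = mn1))
  list(MN1 = mn1, R_A = ra)
}

#' Stage-2 markers for macaque scans
#'
#' The Stage-1 non-brain region is reused unchanged as the background
#' marker.  The brain marker is the bright part of the eroded Stage-1 brain
#' region: the Stage-1 mask is eroded by `stage2_erode_mm`, and voxels of
#' the closed image above the median raw T1 of the Stage-1 region are kept.
#'
#' @param R0 neck-cropped (bias-corrected) T1 [vol3()].
#' @param R_A closed image from [macaque_stage1_markers()].
#' @param B1 Stage-1 brain mask.
#' @inheritParams macaque_stage1_markers
#' @return A list: `MN2`, `M_C`, `t50`.
#' @export
macaque_stage2_markers <- function(R0, R_A, B1, params = macaque_params(),
                                   trace = NULL) {
  if (!any(B1$data)) stop("empty Stage-1 brain region")
  be <- binary_morph(B1, "erode", params$stage2_erode_mm)
  t50 <- quantile_in_mask(R0, B1, 0.5)
  mc <- mask_like(R_A$data > t50 & be$data, B1)
  if (!any(mc$data)) stop("empty Stage-2 brain marker")
  nd <- mask_like(!B1$data, B1)
  mn2 <- merge_markers(mc, nd)
  trace_put(trace, "B_E", be)
  trace_put(trace, "M_C", mc)
  trace_put(trace, "N_D", nd)
  trace_put(trace, "MN_2m", mn2)
  list(MN2 = mn2, M_C = mc, t50 = t50)
}

#' Extract a macaque brain
#'
#' Same two-watershed backbone as the human pipeline with geometry-driven
#' markers: bias correction (recommended -- brightness inhomogeneity can be
#' very severe in macaque scans), neck cropping at 80 mm with a 15 mm
#' anchor slab, the box-based Stage-1 markers, Stage-1 watershed on the
#' inverted T1, then a Stage-2 control built like the human one but without
#' the initial grayscale erosion, and a Stage-2 watershed with no final
#' dilation (nothing was eroded).  The Stage-2 mask is therefore a subset
#' of the Stage-1 mask.  Mask smoothing is off by default.
#'
#' @param v a [vol3()] T1 macaque head volume, canonical orientation.
#' @param params a [macaque_params()] list.
#' @param bias_correct apply [correct_bias()] first.
#' @param smooth also return smoothed masks.
#' @param stages run stage 1 only, or both.
#' @param keep_trace collect intermediates in `$trace`.
#' @return A `scalp_result` list (see [extract_brain_human()]).
#' @export
extract_brain_macaque <- function(v, params = macaque_params(),
                                  bias_correct = TRUE, smooth = FALSE,
                                  stages = 2, keep_trace = FALSE) {
  trace <- if (keep_trace) new.env(parent = emptyenv()) else NULL
  if (bias_correct)
    v <- with_stage("bias correction", correct_bias(v, params$bias_radius_mm))
  cr <- with_stage("neck crop",
                   crop_neck(v, params$crop_extent_mm, params$com_slab_mm))
  r0 <- cr$volume
  trace_put(trace, "R_0", r0)
  mk1 <- with_stage("stage-1 markers",
                    macaque_stage1_markers(r0, cr$com_top, params, trace))
  b1 <- with_stage("stage-1 watershed", stage1_segment(r0, mk1$MN1, trace))
  hp <- human_params(grad_sigma_mm = params$grad_sigma_mm,
                     smooth_open_mm = params$smooth_open_mm,
                     smooth_close_mm = params$smooth_close_mm)
  s1s <- if (smooth) smooth_mask(b1, 1, hp) else NULL
  if (stages < 2) {
    return(structure(list(stage1_mask = b1, stage2_mask = NULL,
                          stage1_smoothed = s1s, stage2_smoothed = NULL,
                          com_top = cr$com_top, trace = trace_list(trace),
                          params = params),
                     class = "scalp_result"))
  }
  mk2 <- with_stage("stage-2 markers",
                    macaque_stage2_markers(r0, mk1$R_A, b1, params, trace))
  rb <- vol_like(r0$data * b1$data, r0)   # no initial erosion
  r2 <- with_stage("stage-2 control",
                   stage2_control(rb, b1, mk2$t50, hp, trace))
  empty <- mask_like(array(FALSE, dim(r0$data)), r0)
  b2 <- with_stage("stage-2 watershed",
                   stage2_segment(r2, mk2$MN2, empty, 0, trace))
  s2s <- if (smooth) smooth_mask(b2, 2, hp) else NULL
  structure(list(stage1_mask = b1, stage2_mask = b2, stage1_smoothed = s1s,
                 stage2_smoothed = s2s, com_top = cr$com_top,
                 trace = trace_list(trace), params = params),
            class = "scalp_result")
}
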