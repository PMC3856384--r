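#' Synthetic head phantom specifications
#'
#' The phantoms emulate the tissue layout the extraction pipelines assume:
#' a bright brain (white core with a gray rim and a ventricle-like internal
#' dark inclusion), a dark CSF/bone gap, a bright scalp (and optionally
#' bright cancellous-bone patches on the inner skull table), a neck or
#' shoulder extension long enough to exercise neck cropping, dark eye
#' globes for the macaque, a multiplicative low-frequency bias field and
#' additive Gaussian noise.  Geometry is nested ellipsoidal shells;
#' intensities are piecewise constant before bias and noise.  The brain
#' truth mask is the pre-noise brain tissue (white + gray + internal CSF +
#' brain stem), voxel exact.
#'
#' The human default is a 1 mm isotropic 150 x 170 x 200 grid whose head
#' spans more than 180 mm superior-inferior, so the neck-crop path really
#' blanks slices.  `marrow_patches > 0` seeds bright patches through the
#' inner skull table adjacent to the CSF gap -- the classic source of
#' false-positive tissue that Stage 2 exists to remove.  Noise defaults to
#' 2 % of the white-matter intensity; Rician statistics are not modelled.
#'
#' @param seed RNG seed fixing patch placement, bias field and noise.
#' @param marrow_patches number of cancellous-bone patches.
#' @param bias_amplitude relative amplitude `a` of the multiplicative bias
#'   field (field spans `[1-a, 1+a]`); 0 disables.
#' @param noise_sd additive Gaussian noise standard deviation, in units of
#'   the white-matter intensity 1.0.
#' @param neck_length_mm length of the neck/shoulder extension.
#' @param spacing voxel size in mm.
#' @param intensities named tissue intensities.
#' @return A `phantom_spec` list.
#' @export
human_phantom_spec <- function(seed = 1, marrow_patches = 0,
                               bias_amplitude = 0, noise_sd = 0.02,
                               neck_length_mm = 70, spacing = c(1, 1, 1),
                               intensities = NULL) {
  ints <- list(white = 1.0, gray = 0.8, deepgray = 0.87, csf = 0.15,
               skull = 0.08, marrow = 1.4, scalp = 0.9, muscle = 0.7,
               air = 0.02)
  if (!is.null(intensities)) ints <- modifyList(ints, intensities)
  structure(list(
    species = "human", seed = as.integer(seed), spacing = check_spacing(spacing),
    dim_mm = c(150, 170, 200),
    brain_semi_mm = c(55, 65, 50), gray_rim_mm = 8, csf_gap_mm = 3,
    skull_mm = 6, scalp_mm = 8,
    deepgray_semi_mm = c(22, 26, 19),
    ventricle_semi_mm = c(10, 14, 7),
    stem_radius_mm = 14, stem_sheath_mm = 3, stem_length_mm = 38,
    neck_radius_mm = 48, neck_length_mm = neck_length_mm,
    marrow_patches = as.integer(marrow_patches), marrow_radius_mm = 7,
    eye_radius_mm = 0,
    bias_amplitude = bias_amplitude, noise_sd = noise_sd,
    intensities = ints), class = "phantom_spec")
}

#' @rdname human_phantom_spec
#' @export
macaque_phantom_spec <- function(seed = 1, bias_amplitude = 0,
                                 noise_sd = 0.015, spacing = c(0.8, 0.8, 0.8),
                                 intensities = NULL) {
  ints <- list(white = 1.0, gray = 0.8, deepgray = 0.87, csf = 0.15,
               skull = 0.12, marrow = 1.4, scalp = 0.9, muscle = 0.7,
               air = 0.04, eye = 0.0)
  if (!is.null(intensities)) ints <- modifyList(ints, intensities)
  structure(list(
    species = "macaque", seed = as.integer(seed),
    spacing = check_spacing(spacing),
    dim_mm = c(86.4, 102.4, 121.6),
    brain_semi_mm = c(25, 31, 22), gray_rim_mm = 5, csf_gap_mm = 2,
    skull_mm = 4, scalp_mm = 8,
    deepgray_semi_mm = c(8, 10, 7),
    ventricle_semi_mm = c(5, 7, 4),
    stem_radius_mm = 7, stem_sheath_mm = 2, stem_length_mm = 16,
    neck_radius_mm = 28, neck_length_mm = 46,
    marrow_patches = 0L, marrow_radius_mm = 5,
    eye_radius_mm = 10,
    bias_amplitude = bias_amplitude, noise_sd = noise_sd,
    intensities = ints), class = "phantom_spec")
}

# Ellipsoid / cylinder helpers over precomputed mm coordinate grids.
ell_mask <- function(gx, gy, gz, centre, semi) {
  outer3 <- outer(outer(((gx - centre[1]) / semi[1])^2,
                        ((gy - centre[2]) / semi[2])^2, "+"),
                  ((gz - centre[3]) / semi[3])^2, "+")
  outer3 <= 1
}

cyl_mask <- function(gx, gy, gz, centre_xy, radius, zlo, zhi) {
  disc <- outer((gx - centre_xy[1])^2, (gy - centre_xy[2])^2, "+") <= radius^2
  zin <- gz >= zlo & gz <= zhi
  outer(disc, zin, "&")
}

sph_mask <- function(gx, gy, gz, centre, radius) {
  ell_mask(gx, gy, gz, centre, rep(radius, 3))
}

#' Generate a synthetic head phantom
#'
#' Builds the tissue-label image for a [human_phantom_spec()] or
#' [macaque_phantom_spec()], assigns the spec's intensities, applies the
#' multiplicative bias field and additive Gaussian noise last (so the truth
#' masks are exact pre-noise tissue labels), and returns the volume with
#' per-tissue ground truth.  Deterministic for a fixed seed; the caller's
#' RNG state is left untouched.
#'
#' @param spec a `phantom_spec`.
#' @return A list: `volume` ([vol3()]), `truth` ([mask3()] of brain
#'   tissue), `tissues` (integer label array with a `levels` attribute),
#'   `bias_field` (array or NULL), `spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  sp <- spec$spacing
  d <- as.integer(round(spec$dim_mm / sp))
  gx <- (seq_len(d[1]) - 1) * sp[1]
  gy <- (seq_len(d[2]) - 1) * sp[2]
  gz <- (seq_len(d[3]) - 1) * sp[3]
  ints <- spec$intensities
  human <- spec$species == "human"

  b <- spec$brain_semi_mm
  csf_o <- b + spec$csf_gap_mm
  skull_o <- csf_o + spec$skull_mm
  scalp_o <- skull_o + spec$scalp_mm
  ctr <- c(spec$dim_mm[1] / 2, spec$dim_mm[2] / 2,
           spec$dim_mm[3] - scalp_o[3] - (if (human) 10 else 7))
  if (any(scalp_o[1:2] >= spec$dim_mm[1:2] / 2))
    stop("phantom geometry violates nesting: head exceeds the grid")

  lev <- c(air = 0L, muscle = 1L, scalp = 2L, skull = 3L, marrow = 4L,
           csf = 5L, gray = 6L, white = 7L, ventricle = 8L, stem = 9L,
           eye = 10L, deepgray = 11L)
  lab <- array(lev[["air"]], d)

  neck_top <- ctr[3] - scalp_o[3] + 12
  neck_lo <- max(0, neck_top - spec$neck_length_mm)
  lab[cyl_mask(gx, gy, gz, c(ctr[1], ctr[2] - 8), spec$neck_radius_mm,
               neck_lo, neck_top)] <- lev[["muscle"]]
  if (!human) {
    # shoulder block at the image bottom and a face block carrying the eyes
    shoulder <- gz <= neck_lo + 14
    lab[, , shoulder] <- lev[["muscle"]]
    face <- outer(outer(abs(gx - ctr[1]) <= 26,
                        gy >= ctr[2] + 18 & gy <= ctr[2] + 46, "&"),
                  gz >= ctr[3] - 32 & gz <= ctr[3] + 0, "&")
    lab[face] <- lev[["muscle"]]
  }

  lab[ell_mask(gx, gy, gz, ctr, scalp_o)] <- lev[["scalp"]]
  lab[ell_mask(gx, gy, gz, ctr, skull_o)] <- lev[["skull"]]
  lab[ell_mask(gx, gy, gz, ctr, csf_o)] <- lev[["csf"]]
  lab[ell_mask(gx, gy, gz, ctr, b)] <- lev[["gray"]]
  lab[ell_mask(gx, gy, gz, ctr, b - spec$gray_rim_mm)] <- lev[["white"]]
  if (any(spec$deepgray_semi_mm > 0))
    lab[ell_mask(gx, gy, gz, ctr + c(0, 0, -2), spec$deepgray_semi_mm)] <-
      lev[["deepgray"]]

  # Brain stem through the skull base, wrapped in a CSF sheath.
  stem_xy <- c(ctr[1], ctr[2] - 8)
  stem_top <- ctr[3] - b[3] + 4
  stem_lo <- stem_top - spec$stem_length_mm
  sheath <- cyl_mask(gx, gy, gz, stem_xy,
                     spec$stem_radius_mm + spec$stem_sheath_mm,
                     stem_lo - spec$stem_sheath_mm, stem_top - 2)
  lab[sheath & lab != lev[["gray"]] & lab != lev[["white"]]] <- lev[["csf"]]
  lab[cyl_mask(gx, gy, gz, stem_xy, spec$stem_radius_mm, stem_lo,
               stem_top)] <- lev[["stem"]]

  lab[ell_mask(gx, gy, gz, ctr + c(0, 0, 3), spec$ventricle_semi_mm)] <-
    lev[["ventricle"]]

  if (spec$marrow_patches > 0) {
    # Patches open through the inner skull table in the superior vault
    # (adjacent to the CSF gap) but keep a cortical shell on the outer
    # side, as thick cancellous bone does.
    skull_zone <- ell_mask(gx, gy, gz, ctr, skull_o - 2) &
      !ell_mask(gx, gy, gz, ctr, csf_o)
    for (i in seq_len(spec$marrow_patches)) {
      phi <- runif(1, 0, 2 * pi)
      pol <- runif(1, 0, 0.45)   # polar angle from vertical: superior cap
      dir <- c(sin(pol) * cos(phi), sin(pol) * sin(phi), cos(pol))
      centre <- ctr + dir * csf_o
      patch <- sph_mask(gx, gy, gz, centre, spec$marrow_radius_mm)
      lab[patch & skull_zone] <- lev[["marrow"]]
    }
  }

  if (!human && spec$eye_radius_mm > 0) {
    for (sgn in c(-1, 1)) {
      eye_c <- c(ctr[1] + sgn * 15, ctr[2] + 35, ctr[3] - 20)
      eye <- sph_mask(gx, gy, gz, eye_c, spec$eye_radius_mm)
      if (any(eye & (lab == lev[["gray"]] | lab == lev[["white"]] |
                       lab == lev[["csf"]])))
        stop("phantom geometry violates nesting: eye touches the brain")
      lab[eye] <- lev[["eye"]]
    }
  }

  vals <- c(ints$air, ints$muscle, ints$scalp, ints$skull, ints$marrow,
            ints$csf, ints$gray, ints$white, ints$csf, ints$white,
            if (!is.null(ints$eye)) ints$eye else ints$air, ints$deepgray)
  img <- array(vals[lab + 1L], d)

  bias <- NULL
  if (spec$bias_amplitude > 0) {
    cf <- runif(3, -1, 1)
    bc <- spec$dim_mm * runif(3, 0.25, 0.75)
    bw <- mean(spec$dim_mm) * 0.4
    lin <- outer(outer(cf[1] * (gx / spec$dim_mm[1] - 0.5),
                       cf[2] * (gy / spec$dim_mm[2] - 0.5), "+"),
                 cf[3] * (gz / spec$dim_mm[3] - 0.5), "+")
    bump <- outer(outer((gx - bc[1])^2, (gy - bc[2])^2, "+"),
                  (gz - bc[3])^2, "+")
    bump <- exp(-bump / (2 * bw^2)) * runif(1, -1, 1)
    raw <- lin + bump
    raw <- raw / max(abs(raw))
    bias <- 1 + spec$bias_amplitude * raw
    img <- img * bias
  }
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(d), 0, spec$noise_sd), d)
  img <- pmax(img, 0)

  truth <- lab == lev[["gray"]] | lab == lev[["white"]] |
    lab == lev[["ventricle"]] | lab == lev[["stem"]] |
    lab == lev[["deepgray"]]
  attr(lab, "levels") <- lev
  list(volume = vol3(img, sp), truth = mask3(array(truth, d), sp),
       tissues = lab, bias_field = bias, spec = spec)
}

#' Overlap scores between a predicted and a truth mask
#'
#' Dice `2|A n B| / (|A| + |B|)`, Jaccard `|A n B| / |A u B|`, sensitivity
#' `|A n B| / |B|` and specificity (true-negative rate over the grid
#' complement of the truth).
#'
#' @param pred,truth [mask3()] objects on the same grid (`truth` is the
#'   reference).
#' @return A list of class `overlap_scores` with elements `dice`,
#'   `jaccard`, `sensitivity`, `specificity`.
#' @export
overlap <- function(pred, truth) {
  stopifnot_same_grid(pred, truth)
  a <- pred$data; b <- truth$data
  if (!any(a) && !any(b)) stop("overlap: both masks are empty")
  inter <- sum(a & b)
  sa <- sum(a); sb <- sum(b)
  un <- sa + sb - inter
  tn <- sum(!a & !b)
  structure(list(dice = 2 * inter / (sa + sb), jaccard = inter / un,
                 sensitivity = inter / sb,
                 specificity = tn / (tn + sum(a & !b))),
            class = "overlap_scores")
}

#' @export
print.overlap_scores <- function(x, ...) {
  cat(sprintf(
    "dice %.4f | jaccard %.4f | sensitivity %.4f | specificity %.4f\n",
    x$dice, x$jaccard, x$sensitivity, x$specificity))
  invisible(x)
}
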