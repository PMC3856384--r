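#' 3D scalar volume
#'
#' A `vol3` is a 3D array of finite scalars together with per-axis voxel
#' spacing in mm and (optionally) a 4x4 affine mapping voxel indices to
#' anatomical coordinates.  Inside the package all volumes are held in a
#' canonical RAS-like order: axis 1 runs left to right, axis 2 posterior to
#' anterior, axis 3 inferior to superior, so that "superior" always means
#' increasing index along the third axis.  [read_volume()] performs the
#' reorientation; volumes built in code are assumed canonical already.
#'
#' @param data 3D numeric array; all values must be finite.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param affine optional 4x4 affine (RAS); defaults to a diagonal affine
#'   built from `spacing`.
#' @param io internal bookkeeping used to restore a file's original
#'   orientation on write; leave `NULL` for synthetic volumes.
#' @return An object of class `vol3` with elements `data`, `spacing`,
#'   `affine`, `io`.
#' @seealso [mask3()], [read_volume()]
#' @export
vol3 <- function(data, spacing = c(1, 1, 1), affine = NULL, io = NULL) {
  data <- as_array3(data, "numeric")
  if (anyNA(data) || !all(is.finite(data)))
    stop("volume data must be finite (no NA/NaN/Inf)")
  spacing <- check_spacing(spacing)
  if (is.null(affine)) affine <- spacing_affine(spacing)
  structure(list(data = data, spacing = spacing, affine = affine, io = io),
            class = "vol3")
}

#' Binary mask on a volume's grid
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @inheritParams vol3
#' @return An object of class `mask3`.
#' @export
mask3 <- function(data, spacing = c(1, 1, 1), affine = NULL, io = NULL) {
  data <- as_array3(data, "logical")
  if (anyNA(data)) stop("mask data must not contain NA")
  spacing <- check_spacing(spacing)
  if (is.null(affine)) affine <- spacing_affine(spacing)
  structure(list(data = data, spacing = spacing, affine = affine, io = io),
            class = "mask3")
}

#' @export
print.vol3 <- function(x, ...) {
  cat("<vol3> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.mask3 <- function(x, ...) {
  cat("<mask3> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$data), " foreground voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.vol3 <- function(x) dim(x$data)

#' @export
dim.mask3 <- function(x) dim(x$data)

as_array3 <- function(data, mode) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("expected a 3D array")
  if (any(dim(data) < 1L)) stop("each axis must have extent >= 1")
  storage.mode(data) <- if (mode == "logical") "logical" else "double"
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm")
  spacing
}

spacing_affine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

# Rewrap an array using the grid metadata of an existing vol3/mask3.
# Internal fast paths: inputs come from already-validated package code, so
# the constructor checks are skipped.
vol_like <- function(data, like) {
  if (is.null(dim(data))) dim(data) <- dim(like$data)
  structure(list(data = data, spacing = like$spacing, affine = like$affine,
                 io = like$io), class = "vol3")
}
mask_like <- function(data, like) {
  if (is.null(dim(data))) dim(data) <- dim(like$data)
  structure(list(data = data, spacing = like$spacing, affine = like$affine,
                 io = like$io), class = "mask3")
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grids differ in shape: ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("grids differ in spacing")
  invisible(TRUE)
}

# Physical mm coordinate of a (possibly fractional) 1-based voxel index in
# the canonical internal frame.
index_to_mm <- function(index, spacing) (index - 1) * spacing
mm_to_index <- function(mm, spacing) mm / spacing + 1

#' Marker image for the watershed transform
#'
#' Combine a brain marker and a background marker into a single label image:
#' brain voxels get label 1, background voxels label 2 and all remaining
#' voxels 0.  The two masks must be disjoint.
#'
#' @param brain,background `mask3` objects on the same grid.
#' @return Integer label array of class `markers3` (spacing attached).
#' @export
merge_markers <- function(brain, background) {
  stopifnot_same_grid(brain, background)
  if (any(brain$data & background$data))
    stop("brain and background markers overlap")
  lab <- array(0L, dim(brain$data))
  lab[brain$data] <- 1L
  lab[background$data] <- 2L
  structure(list(data = lab, spacing = brain$spacing, affine = brain$affine,
                 io = brain$io),
            class = "markers3")
}

#' @export
print.markers3 <- function(x, ...) {
  tab <- table(factor(x$data[x$data > 0]))
  cat("<markers3> ", paste(dim(x$data), collapse = " x "), " voxels; ",
      paste(sprintf("label %s: %d", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.markers3 <- function(x) dim(x$data)
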