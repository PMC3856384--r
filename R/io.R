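#' Read a NIfTI volume
#'
#' Reads a 3D (or 4D with a singleton trailing dimension) NIfTI-1/2 file
#' and reorients the data internally to the canonical RAS-like order the
#' pipelines assume (left-right, posterior-anterior, inferior-superior).
#' The original orientation is remembered so masks written with
#' [write_mask()] come back on the input grid in the input orientation.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [vol3()] in canonical orientation.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), dm[1:3]), reference = img)
    dm <- dim(img)
  }
  if (length(dm) != 3L)
    stop("expected a 3D volume, got ", length(dm), " dimensions")
  xf <- RNifti::xform(img)
  if (isTRUE(attr(xf, "code") == 0))
    stop("NIfTI file has no affine (qform and sform codes are both 0)")
  orig <- RNifti::orientation(img)
  RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  vol3(arr, spacing, aff, io = list(orientation = orig))
}

nifti_with_grid <- function(arr, like, datatype) {
  attr(arr, "pixdim") <- like$spacing
  img <- RNifti::asNifti(arr, datatype = datatype)
  aff <- like$affine
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  orig <- like$io$orientation
  if (!is.null(orig) && !identical(orig, "RAS"))
    RNifti::orientation(img) <- orig
  img
}

#' Write a mask or a volume to NIfTI
#'
#' Masks are written as uint8 in \{0, 1\}; volumes as float32.  Data are
#' mapped back from the canonical internal orientation to the orientation
#' of the originating file (when the grid came from [read_volume()]), so
#' the written header matches the input's.
#'
#' @param m a [mask3()].
#' @param v a [vol3()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param like optional grid reference (defaults to the object itself);
#'   must match the object's grid.
#' @return The path, invisibly.
#' @export
write_mask <- function(m, path, like = NULL) {
  if (!is.null(like)) stopifnot_same_grid(m, like) else like <- m
  arr <- array(as.integer(m$data), dim(m$data))
  img <- nifti_with_grid(arr, like, "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
write_volume <- function(v, path, like = NULL) {
  if (!is.null(like)) stopifnot_same_grid(v, like) else like <- v
  img <- nifti_with_grid(v$data, like, "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}
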