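#' 4D BOLD container
#'
#' A `bold4d` bundles a subject's 4D BOLD array (x, y, z, t) with its
#' voxel-to-world affine and repetition time.  It is the unit every
#' preprocessing stage and the GFC computation operate on.
#'
#' @param data Numeric 4D array, dimensions (x, y, z, t) with t >= 2.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices map to
#'   world mm coordinates).
#' @param tr Repetition time in seconds (> 0).
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, affine = diag(4), tr = 2) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_input("`data` must be a 4D array (x, y, z, t); got %s dims",
               length(dim(data)))
  if (dim(data)[4] < 2L) stop_input("need at least 2 time points")
  if (!all(is.finite(data))) stop_input("BOLD data contain non-finite values")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop_input("`affine` must be 4x4")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop_input("`tr` must be > 0")
  structure(list(data = data, affine = affine, tr = as.numeric(tr)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

n_volumes <- function(bold) dim(bold$data)[4]

# flatten to (t x V) matrix for the voxels in `vox` (integer matrix, 1-based)
bold_matrix <- function(bold, vox) {
  d <- dim(bold$data)
  nt <- d[4]
  lin <- (vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2])
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = nt)
  t(m[lin, , drop = FALSE])
}

# drop RNifti bookkeeping attributes so the affine is a plain 4x4 matrix
strip_affine <- function(m) matrix(as.numeric(m), 4, 4)

#' Read and write 4D BOLD volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} that preserve the data array, the
#' voxel-to-world affine (sform/qform) and the repetition time (the 4th
#' pixdim entry) through a write/read round trip.  Both plain `.nii` and
#' gzipped `.nii.gz` files are accepted.
#'
#' @param path Path to a NIfTI-1 file.
#' @return `read_bold()` returns a [bold4d]; `write_bold()` returns `path`
#'   invisibly.
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop_input("expected a 4D volume at %s; got %d dimension(s) %s",
               path, length(d), paste(d, collapse = "x"))
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  bold4d(array(as.numeric(img), dim = d), affine = strip_affine(RNifti::xform(img)),
         tr = tr)
}

#' @param bold A [bold4d].
#' @rdname read_bold
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  img <- RNifti::`qform<-`(img, structure(bold$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(bold$affine, code = 2L))
  # voxel sizes live in pixdim and override the qform scale on write
  RNifti::pixdim(img) <- c(sqrt(colSums(bold$affine[1:3, 1:3]^2)), bold$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write 3D volumes (masks, probability maps, statistic maps)
#'
#' @param path File path.
#' @return `read_volume()` returns a list with `data` (3D array) and
#'   `affine`; `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_input("expected a 3D volume at %s; got dims %s", path,
               paste(d, collapse = "x"))
  list(data = array(as.numeric(img), dim = d),
       affine = strip_affine(RNifti::xform(img)))
}

#' @param vol 3D numeric array.
#' @param affine 4x4 voxel-to-world transform.
#' @rdname read_volume
#' @export
write_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(vol)
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write rigid-body motion parameter traces
#'
#' Motion traces use the 6-column whitespace text dialect written by SPM-style
#' realignment (`rp_*.txt`): three translations in mm then three rotations in
#' radians, one row per volume.
#'
#' @param path File path.
#' @return `read_motion()` returns a `motion_trace` (list with `params`, a
#'   T x 6 matrix).
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop_input("motion file %s has %d columns; expected 6", path, ncol(m))
  motion_trace(m)
}

#' @param motion A `motion_trace`.
#' @rdname read_motion
#' @export
write_motion <- function(motion, path) {
  write.table(format(motion$params, digits = 10, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Motion trace container
#'
#' @param params T x 6 numeric matrix: translations (mm) in columns 1-3,
#'   rotations (radians) in columns 4-6.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop_input("motion params must have 6 columns")
  if (!all(is.finite(params))) stop_input("motion params contain non-finite values")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(list(params = params), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames\n", nrow(x$params)))
  invisible(x)
}
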