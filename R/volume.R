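#' Construct a masked 4D BOLD volume
#'
#' The basic container carried through the pipeline: an `X x Y x Z x T`
#' numeric array with its voxel-to-mm affine, repetition time and a 3D
#' brain mask. All pipeline stages accept and return this class.
#'
#' @param data Numeric 4D array, `X x Y x Z x T`.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices). Defaults
#'   to 3 mm isotropic voxels with the origin at voxel (0,0,0).
#' @param tr Repetition time in seconds.
#' @param mask Logical 3D array matching the spatial grid; defaults to
#'   all-`TRUE`.
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(data, affine = NULL, tr = 2, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (X x Y x Z x T)")
  dims <- dim(data)
  if (dims[4] < 2L) stop("volume must have T >= 2 time points")
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  mask <- array(as.logical(mask), dims[1:3])
  if (!any(mask)) stop("`mask` must contain at least one voxel")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)")
  structure(list(data = data, affine = affine, tr = tr, mask = mask),
            class = "bold_volume")
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_volume> %d x %d x %d x %d, TR = %g s, %d voxels in mask\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Construct a 3D statistic map sharing a volume's grid
#'
#' @param values Numeric 3D array (ReHo, t, z(FC), ... values).
#' @param mask Logical 3D array of valid voxels.
#' @param affine 4x4 voxel-to-mm affine.
#' @param kind Character tag describing what the values are
#'   (e.g. `"reho"`, `"mreho"`, `"szreho"`, `"r"`, `"zfc"`, `"t"`).
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, mask, affine = diag(c(3, 3, 3, 1)),
                     kind = "stat") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  mask <- array(as.logical(mask), dim(values))
  structure(list(values = values, mask = mask, affine = as.matrix(affine),
                 kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$mask]
  cat(sprintf("<stat_map:%s> %d x %d x %d, %d in-mask voxels, range [%.4g, %.4g]\n",
              x$kind, d[1], d[2], d[3], sum(x$mask), min(v), max(v)))
  invisible(x)
}

#' Extract the in-mask voxel-by-time matrix of a volume
#'
#' @param vol A [bold_volume].
#' @return A `T x V` matrix, columns ordered as `which(vol$mask)`.
#' @export
mask_matrix <- function(vol) {
  stopifnot(inherits(vol, "bold_volume"))
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  t(m[as.vector(vol$mask), , drop = FALSE])
}

#' Replace the in-mask voxel-by-time matrix of a volume
#'
#' Inverse of [mask_matrix()]: writes a `T x V` matrix back into the 4D
#' grid (out-of-mask voxels are zeroed).
#' @param vol A [bold_volume].
#' @param mat `T x V` matrix with `V = sum(vol$mask)`.
#' @return A [bold_volume] with the same grid metadata.
#' @export
set_mask_matrix <- function(vol, mat) {
  d <- dim(vol$data)
  stopifnot(ncol(mat) == sum(vol$mask), nrow(mat) == d[4])
  out <- matrix(0, prod(d[1:3]), d[4])
  out[as.vector(vol$mask), ] <- t(mat)
  bold_volume(array(out, d), vol$affine, vol$tr, vol$mask)
}

#' Map voxel indices to mm coordinates via the affine
#'
#' @param ijk Integer matrix (rows = voxels, columns = 1-based array
#'   indices) or a length-3 vector.
#' @param affine 4x4 voxel-to-mm affine using 0-based voxel indices.
#' @return Matrix of mm coordinates (rows match `ijk`).
#' @export
voxel_to_mm <- function(ijk, affine) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)  # 0-based convention
  xyz1[, 1:3, drop = FALSE]
}

#' Write a volume or map to a NIfTI-1 file
#'
#' @param x A [bold_volume] or [stat_map].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "bold_volume")) {
    arr <- x$data; aff <- x$affine; tr <- x$tr
  } else if (inherits(x, "stat_map")) {
    arr <- x$values; aff <- x$affine; tr <- 0
  } else stop("`x` must be a bold_volume or stat_map")
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  if (tr > 0) RNifti::pixdim(img)[4] <- tr
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file into a volume or map
#'
#' 4D images become [bold_volume]s (an all-`TRUE` mask unless `mask` is
#' given); 3D images become [stat_map]s.
#'
#' @param path NIfTI file path.
#' @param mask Optional logical array or path to a mask NIfTI.
#' @param tr Repetition time override (seconds); defaults to the file's
#'   pixdim.
#' @return A [bold_volume] or [stat_map].
#' @export
read_nifti_volume <- function(path, mask = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  if (is.character(mask)) mask <- RNifti::readNifti(mask) > 0
  arr <- unclass(as.array(img))
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L) {
    if (is.null(tr)) {
      tr <- RNifti::pixdim(img)[4]
      if (!is.finite(tr) || tr <= 0) tr <- 2
    }
    bold_volume(arr, aff, tr, mask)
  } else {
    if (is.null(mask)) mask <- array(TRUE, dim(arr))
    stat_map(arr, mask, aff)
  }
}

# deterministic per-subject seed derived from a master seed (kept < 2^31)
derive_seed <- function(master, salt) {
  as.integer((as.numeric(master) * 10007 + 7919 * as.numeric(salt)) %% 2147483647)
}
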