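#' 3D image volume with physical voxel size
#'
#' Light-weight container for a 3D voxel grid carrying activity
#' (kBq/ml), Hounsfield units, linear attenuation (1/mm), material
#' labels, or a sensitivity image.  The volume is centred on the origin:
#' voxel `(i, j, k)` (1-based) has its centre at
#' `(i - (n + 1) / 2) * voxel_size` mm per axis.
#'
#' @param values 3D numeric array (a matrix is promoted to a single-plane
#'   volume).
#' @param voxel_size voxel edge length in mm; scalar or length-3.
#' @param kind content kind, one of `"activity"`, `"hu"`, `"mu"`,
#'   `"label"`, `"sensitivity"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values,
                         voxel_size = 2,
                         kind = c("activity", "hu", "mu", "label",
                                  "sensitivity")) {
  kind <- match.arg(kind)
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive")
  if (any(dim(values) < 1L)) stop("all grid dimensions must be >= 1")
  if (kind == "activity" && any(values < 0))
    stop("activity volumes must be non-negative")
  structure(list(values = values, voxel_size = voxel_size, kind = kind),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume [%s]> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$kind, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  range [%.4g, %.4g], sum %.6g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

# replace the voxel data, keeping grid metadata
vol_like <- function(vol, values, kind = vol$kind) {
  v <- vol
  v$values <- array(values, dim = dim(vol$values))
  v$kind <- kind
  v
}

#' Physical voxel-centre coordinates along one axis
#'
#' @param vol an [image_volume()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of centre coordinates in mm.
#' @export
voxel_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  (seq_len(n) - (n + 1) / 2) * vol$voxel_size[axis]
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

#' Write a volume to NIfTI
#'
#' @param vol an [image_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param kind content kind of the stored volume.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, kind = "activity") {
  img <- RNifti::readNifti(path)
  vx <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               voxel_size = vx, kind = kind)
}
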