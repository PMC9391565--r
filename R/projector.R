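#' Parallel-beam multi-slice scanner geometry
#'
#' Stacked-2D parallel-beam geometry: `n_angles` views over `[0, pi)`,
#' `n_radial` radial bins of `radial_spacing` mm, one sinogram plane per
#' image plane.  The geometry is bound to an image grid so that forward
#' and back projection form an exact transpose pair.
#'
#' @param image_dim image grid dimensions, length 3; the axial plane
#'   count of the sinogram equals `image_dim[3]`.
#' @param voxel_size image voxel size in mm.
#' @param n_angles number of projection angles over `[0, pi)`.
#' @param n_radial number of radial bins (default: image width).
#' @param radial_spacing radial bin width in mm (default: voxel size).
#' @return An object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(image_dim, voxel_size = 2,
                             n_angles = 96L, n_radial = NULL,
                             radial_spacing = NULL) {
  image_dim <- as.integer(image_dim)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(n_radial)) n_radial <- image_dim[1]
  if (is.null(radial_spacing)) radial_spacing <- voxel_size[1]
  structure(list(image_dim = image_dim, voxel_size = voxel_size,
                 n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 radial_spacing = as.numeric(radial_spacing),
                 angles = (seq_len(n_angles) - 1L) * pi / n_angles),
            class = "scanner_geometry")
}

projection_data <- function(values, geometry, angle_idx = NULL,
                            is_noisy = FALSE) {
  structure(list(values = values, geometry = geometry,
                 angle_idx = angle_idx, is_noisy = is_noisy),
            class = "projection_data")
}

#' @export
print.projection_data <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<projection_data%s> %d radial x %d angles x %d planes, sum %.6g\n",
              if (x$is_noisy) " (noisy)" else "", d[1], d[2], d[3],
              sum(x$values)))
  invisible(x)
}

check_fov <- function(image, geometry) {
  if (!identical(dim(image$values), geometry$image_dim) ||
      !isTRUE(all.equal(image$voxel_size, geometry$voxel_size)))
    stop("image grid does not match the geometry FOV")
}

#' Forward projection (system matrix factor X)
#'
#' Per-LOR line integrals in mm via ray tracing with exact voxel
#' intersection lengths.
#'
#' @param image an [image_volume()].
#' @param geometry a [scanner_geometry()].
#' @param angle_idx optional 1-based angle subset (default: all angles).
#' @return A `projection_data` with dimensions
#'   `n_radial x length(angle_idx) x n_planes`.
#' @export
forward_project <- function(image, geometry, angle_idx = NULL) {
  check_fov(image, geometry)
  if (is.null(angle_idx)) angle_idx <- seq_len(geometry$n_angles)
  v <- cpp_forward_project(as.numeric(image$values), geometry$image_dim,
                           geometry$voxel_size, geometry$angles[angle_idx],
                           geometry$n_radial, geometry$radial_spacing)
  projection_data(array(v, dim = c(geometry$n_radial, length(angle_idx),
                                   geometry$image_dim[3])),
                  geometry, angle_idx)
}

#' Back projection (exact transpose of [forward_project()])
#'
#' @param proj a `projection_data` (values array also accepted together
#'   with `angle_idx`).
#' @param geometry a [scanner_geometry()].
#' @param angle_idx 1-based angle subset matching the sinogram's second
#'   dimension (default: taken from `proj`, else all angles).
#' @return An [image_volume()] (kind `"sensitivity"`).
#' @export
back_project <- function(proj, geometry, angle_idx = NULL) {
  vals <- if (inherits(proj, "projection_data")) proj$values else proj
  if (is.null(angle_idx))
    angle_idx <- if (inherits(proj, "projection_data") &&
                       !is.null(proj$angle_idx)) proj$angle_idx
                 else seq_len(geometry$n_angles)
  if (dim(vals)[2] != length(angle_idx))
    stop("sinogram angle dimension does not match `angle_idx`")
  v <- cpp_back_project(as.numeric(vals), geometry$image_dim,
                        geometry$voxel_size, geometry$angles[angle_idx],
                        geometry$n_radial, geometry$radial_spacing)
  image_volume(array(v, dim = geometry$image_dim), geometry$voxel_size,
               kind = "sensitivity")
}

#' Per-LOR attenuation factors (system matrix factor W)
#'
#' `exp(-integral of mu dl)` per LOR, using the same ray tracer as the
#' geometric projector.
#'
#' @param mu attenuation [image_volume()] in 1/mm.
#' @param geometry a [scanner_geometry()].
#' @return Array `n_radial x n_angles x n_planes` of factors in (0, 1].
#' @export
attenuation_factors <- function(mu, geometry) {
  if (any(mu$values < 0)) stop("negative attenuation coefficients")
  p <- forward_project(mu, geometry)
  exp(-p$values)
}

gaussian_kernel_1d <- function(fwhm, voxel) {
  if (fwhm == 0) return(1)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel
  h <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Detector point-spread-function blur
#'
#' Isotropic stationary Gaussian blur of the stated FWHM, applied in
#' image space as the detector-resolution factor of H.  The truncated
#' discrete kernel is unit-sum, so interior-supported images are
#' conserved; the symmetric kernel makes the operator self-adjoint.
#'
#' @param image an [image_volume()].
#' @param fwhm full width at half maximum in mm (`0` is the identity).
#' @return Blurred [image_volume()].
#' @export
detector_blur <- function(image, fwhm) {
  if (fwhm < 0) stop("`fwhm` must be >= 0")
  if (fwhm == 0) return(image)
  ks <- lapply(image$voxel_size, function(v) gaussian_kernel_1d(fwhm, v))
  out <- cpp_separable_blur(as.numeric(image$values), dim(image$values),
                            ks[[1]], ks[[2]], ks[[3]])
  vol_like(image, out)
}

#' Partition projection angles into ordered subsets
#'
#' Interleaved assignment (subset k takes angles congruent to k modulo
#' the subset count) with a maximal-angular-distance processing order so
#' that consecutive updates use maximally complementary views.
#'
#' @param geometry a [scanner_geometry()].
#' @param n_subsets number of subsets; must divide `n_angles`.
#' @return An object of class `subset_scheme`: list with `subsets`
#'   (list of 1-based angle index vectors) and `order` (processing
#'   permutation of the subsets).
#' @export
partition_subsets <- function(geometry, n_subsets = 12L) {
  na <- geometry$n_angles
  n_subsets <- as.integer(n_subsets)
  if (na %% n_subsets != 0L)
    stop("`n_angles` must be divisible by `n_subsets`")
  subsets <- lapply(seq_len(n_subsets) - 1L,
                    function(k) seq(k + 1L, na, by = n_subsets))
  # greedy maximal-angular-distance ordering over the subsets' first angles
  pos <- (seq_len(n_subsets) - 1L) / n_subsets  # circular in [0, 1)
  ord <- 1L
  while (length(ord) < n_subsets) {
    remaining <- setdiff(seq_len(n_subsets), ord)
    score <- vapply(remaining, function(r) {
      d <- abs(pos[r] - pos[ord])
      min(pmin(d, 1 - d))
    }, numeric(1))
    ord <- c(ord, remaining[which.max(score)])
  }
  structure(list(subsets = subsets, order = ord, n_subsets = n_subsets),
            class = "subset_scheme")
}

#' Factorized system model A = W * X * H
#'
#' @param geometry a [scanner_geometry()].
#' @param attenuation optional per-LOR attenuation/sensitivity factor
#'   array from [attenuation_factors()] (default: all 1).
#' @param detector_fwhm detector PSF FWHM in mm (0 disables PSF).
#' @param pr optional positron-range model: a list with `bank` (a
#'   [build_kernel_bank()] result) and `material_map` (label volume).
#' @param norm per-LOR efficiency factors (default 1).
#' @return An object of class `system_model`.
#' @export
system_model <- function(geometry, attenuation = NULL, detector_fwhm = 0,
                         pr = NULL, norm = 1) {
  if (detector_fwhm < 0) stop("`detector_fwhm` must be >= 0")
  if (!is.null(attenuation)) {
    if (any(attenuation <= 0) || any(attenuation > 1 + 1e-12))
      stop("attenuation factors must lie in (0, 1]")
  }
  if (!is.null(pr)) {
    if (!inherits(pr$bank, "kernel_bank") ||
        !inherits(pr$material_map, "image_volume"))
      stop("`pr` must hold a kernel bank and a material map")
    pr$material_map <- cache_homog(pr$material_map,
                                   dim(pr$bank$kernels[[1]]$values))
  }
  structure(list(geometry = geometry, attenuation = attenuation,
                 detector_fwhm = detector_fwhm, pr = pr, norm = norm),
            class = "system_model")
}

# per-LOR multiplicative weights (attenuation x normalization) for an
# angle subset; returns scalar 1 when both are trivial
model_weights <- function(model, angle_idx) {
  w <- model$norm
  if (!is.null(model$attenuation)) {
    a <- model$attenuation[, angle_idx, , drop = FALSE]
    w <- if (identical(w, 1)) a else w * a
  }
  w
}

#' Simulate a PET acquisition
#'
#' Generates the expected sinogram `W * X * H(activity)` with the
#' positron-range blur of the model's ground-truth material map and the
#' detector PSF applied in image space, scales it so its total equals
#' `total_counts`, and (unless `noiseless`) draws independent Poisson
#' counts per bin.
#'
#' @param phantom a `phantom_set` (or an activity [image_volume()]).
#' @param model a [system_model()]; its `pr` slot provides the
#'   ground-truth positron-range blur (omit for a range-free simulation).
#' @param total_counts expected total number of detected counts.
#' @param seed RNG seed for the Poisson draw.
#' @param noiseless if `TRUE`, return the expectation itself.
#' @return A `projection_data`; the scale factor applied to the
#'   expectation is stored in attribute `"count_scale"`.
#' @export
simulate_acquisition <- function(phantom, model, total_counts,
                                 seed = 1L, noiseless = FALSE) {
  if (total_counts <= 0) stop("`total_counts` must be positive")
  act <- if (inherits(phantom, "phantom_set")) phantom$activity else phantom
  img <- act
  if (!is.null(model$pr))
    img <- apply_pr_blur(img, model$pr$material_map, model$pr$bank)
  if (model$detector_fwhm > 0)
    img <- detector_blur(img, model$detector_fwhm)
  p <- forward_project(img, model$geometry)
  w <- model_weights(model, seq_len(model$geometry$n_angles))
  expect <- p$values * w
  s <- sum(expect)
  if (s <= 0) stop("zero expected counts; check the phantom/model")
  scale <- total_counts / s
  expect <- expect * scale
  if (noiseless) {
    out <- projection_data(expect, model$geometry, is_noisy = FALSE)
  } else {
    set.seed(seed)
    counts <- array(rpois(length(expect), expect), dim = dim(expect))
    out <- projection_data(counts, model$geometry, is_noisy = TRUE)
  }
  attr(out, "count_scale") <- scale
  out
}
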