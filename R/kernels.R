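#' Positron-range kernel
#'
#' An odd-sized, non-negative, unit-sum 3D blurring kernel: entry `h` is
#' the probability that a positron emitted in the centre voxel annihilates
#' in the voxel at offset `h`.
#'
#' @param values 3D array of probabilities, odd size per axis.
#' @param voxel_size voxel size in mm (scalar or length 3).
#' @param material_tag one of the material names or `"composed"`.
#' @param discarded_fraction fraction of Monte-Carlo events that fell
#'   outside the kernel support (lost and renormalized away).
#' @return An object of class `pr_kernel`.
#' @export
pr_kernel <- function(values, voxel_size, material_tag = "composed",
                      discarded_fraction = NA_real_) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) %% 2L == 0L))
    stop("kernel size must be odd per axis (no centre voxel otherwise)")
  if (any(values < 0)) stop("kernel values must be non-negative")
  s <- sum(values)
  if (s <= 0) stop("kernel must have positive total mass")
  values <- values / s
  structure(list(values = values,
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 material_tag = material_tag,
                 discarded_fraction = discarded_fraction),
            class = "pr_kernel")
}

#' @export
print.pr_kernel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pr_kernel [%s]> %dx%dx%d, voxel %.3g mm, centre mass %.3f",
              x$material_tag, d[1], d[2], d[3], x$voxel_size[1],
              x$values[(d[1] + 1) / 2, (d[2] + 1) / 2, (d[3] + 1) / 2]))
  if (is.finite(x$discarded_fraction))
    cat(sprintf(", discarded %.1f%%", 100 * x$discarded_fraction))
  cat("\n")
  invisible(x)
}

#' Build a uniform material positron-range kernel by Monte Carlo
#'
#' Simulates `n_events` annihilation displacements in a uniform material
#' (see [sample_annihilation_displacement()]) and bins them onto the voxel
#' grid centred on the emission voxel.  Events outside the kernel support
#' are discarded and the kernel renormalized to unit sum; the discarded
#' fraction is recorded (large for lung, where the range exceeds the
#' default 11x11x11 support that is kept deliberately small because larger
#' supports trade accuracy near interfaces for reconstruction artifacts).
#'
#' @param spectrum a [positron_spectrum()].
#' @param material a [material_spec()].
#' @param voxel_size voxel size in mm.
#' @param kernel_size odd integer (scalar or length 3), default 11.
#' @param n_events number of simulated annihilations.
#' @param seed RNG seed; fully determines the kernel.
#' @param tortuosity see [sample_annihilation_displacement()].
#' @return A [pr_kernel()].
#' @export
build_uniform_kernel <- function(spectrum, material, voxel_size = 2,
                                 kernel_size = 11L, n_events = 1e5,
                                 seed = 1L, tortuosity = 0.9) {
  ks <- rep_len(as.integer(kernel_size), 3L)
  if (any(ks %% 2L == 0L)) stop("`kernel_size` must be odd per axis")
  if (n_events < 1) stop("`n_events` must be >= 1")
  vx <- rep_len(as.numeric(voxel_size), 3L)
  set.seed(seed)
  d <- sample_annihilation_displacement(spectrum, material$mass_density,
                                        n = n_events, tortuosity = tortuosity)
  half <- (ks - 1L) %/% 2L
  idx <- round(sweep(d, 2, vx, "/"))
  keep <- abs(idx[, 1]) <= half[1] & abs(idx[, 2]) <= half[2] &
    abs(idx[, 3]) <= half[3]
  discarded <- 1 - mean(keep)
  idx <- idx[keep, , drop = FALSE]
  lin <- (idx[, 1] + half[1]) + ks[1] * ((idx[, 2] + half[2]) +
                                           ks[2] * (idx[, 3] + half[3])) + 1
  counts <- tabulate(lin, nbins = prod(ks))
  pr_kernel(array(counts, dim = ks), voxel_size = vx,
            material_tag = material$name, discarded_fraction = discarded)
}

#' Build a bank of uniform kernels for a material set
#'
#' @param spectrum a [positron_spectrum()] (default I-124).
#' @param materials named list of [material_spec()]s
#'   (default [default_materials()]).
#' @param voxel_size,kernel_size,n_events,tortuosity passed to
#'   [build_uniform_kernel()].
#' @param seed single seed determining the whole bank (per-material
#'   sub-seeds are derived from it).
#' @return An object of class `kernel_bank`: a list with `kernels`
#'   (named list of [pr_kernel()]s), `materials`, `isotope`, `n_events`
#'   and `seed`.
#' @export
build_kernel_bank <- function(spectrum = i124_positron_spectrum(),
                              materials = default_materials(),
                              voxel_size = 2, kernel_size = 11L,
                              n_events = 2e5, seed = 1L, tortuosity = 0.9) {
  validate_materials(materials)
  kernels <- vector("list", length(materials))
  names(kernels) <- names(materials)
  for (i in seq_along(materials))
    kernels[[i]] <- build_uniform_kernel(spectrum, materials[[i]],
                                         voxel_size = voxel_size,
                                         kernel_size = kernel_size,
                                         n_events = n_events,
                                         seed = seed + (i - 1L),
                                         tortuosity = tortuosity)
  structure(list(kernels = kernels, materials = materials,
                 isotope = spectrum$isotope, n_events = n_events,
                 seed = seed),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("<kernel_bank> %s, %d materials (%s), %g events, seed %d\n",
              x$isotope, length(x$kernels),
              paste(names(x$kernels), collapse = ", "), x$n_events, x$seed))
  invisible(x)
}

# stack bank kernels into a K3 x n_material matrix matching the label
# levels of a material map; errors on labels missing from the bank
bank_matrix <- function(bank, material_map) {
  levels <- attr(material_map$values, "materials")
  if (is.null(levels)) levels <- names(bank$kernels)
  missing <- setdiff(levels, names(bank$kernels))
  if (length(missing))
    stop("material label(s) not covered by the kernel bank: ",
         paste(missing, collapse = ", "))
  ks <- dim(bank$kernels[[1]]$values)
  mat <- vapply(levels, function(nm) as.numeric(bank$kernels[[nm]]$values),
                numeric(prod(ks)))
  list(kernels = mat, ksize = ks, levels = levels)
}

map_labels0 <- function(material_map) {
  as.integer(material_map$values) - 1L
}

#' Compose the spatially variant kernel at one voxel
#'
#' For kernel offset `h`, takes the uniform-kernel value of the material
#' found at the destination voxel (`voxel_index + h`, clamped to the
#' volume at the edges) and renormalizes to unit sum.  In a homogeneous
#' region this reproduces the uniform material kernel exactly.
#'
#' @param bank a [build_kernel_bank()] result.
#' @param material_map label [image_volume()] from [segment_materials()].
#' @param voxel_index 1-based voxel index, length 3.
#' @return A [pr_kernel()] with `material_tag = "composed"`.
#' @export
compose_voxel_kernel <- function(bank, material_map, voxel_index) {
  d <- dim(material_map$values)
  voxel_index <- as.integer(voxel_index)
  if (length(voxel_index) != 3L || any(voxel_index < 1L) ||
      any(voxel_index > d))
    stop("`voxel_index` outside the volume")
  bm <- bank_matrix(bank, material_map)
  vals <- cpp_compose_kernel(map_labels0(material_map), d, bm$kernels,
                             bm$ksize, voxel_index - 1L)
  pr_kernel(array(vals, dim = bm$ksize),
            voxel_size = bank$kernels[[1]]$voxel_size,
            material_tag = "composed")
}

pr_blur_impl <- function(image, material_map, bank, adjoint, mask = NULL) {
  if (!same_grid(image, material_map))
    stop("image and material map must share the voxel grid")
  bm <- bank_matrix(bank, material_map)
  labels0 <- map_labels0(material_map)
  homog <- attr(material_map, "homog_cache")
  if (is.null(homog))
    homog <- cpp_homog_map(labels0, dim(image$values),
                           (bm$ksize - 1L) %/% 2L)
  mask <- if (is.null(mask)) logical(0) else as.logical(mask)
  out <- cpp_pr_blur(as.numeric(image$values), dim(image$values), labels0,
                     homog, bm$kernels, bm$ksize, adjoint, mask)
  vol_like(image, out)
}

#' Apply the spatially variant positron-range blur
#'
#' Spreads each source voxel's content over its neighbours according to
#' the kernel composed at that source voxel ("spread from source", which
#' conserves emitted counts).  Mass crossing the volume edge is lost,
#' mirroring out-of-FOV annihilations; for interior-supported images the
#' total is conserved.
#'
#' @param image activity [image_volume()].
#' @param material_map label volume from [segment_materials()], same grid.
#' @param bank a [build_kernel_bank()] result.
#' @return Blurred [image_volume()].
#' @export
apply_pr_blur <- function(image, material_map, bank) {
  pr_blur_impl(image, material_map, bank, adjoint = FALSE)
}

#' Exact adjoint of the positron-range blur
#'
#' The matrix transpose of [apply_pr_blur()] on the voxel grid: a gather
#' at each voxel with the kernel composed there.  Needed by the
#' back-projection and sensitivity terms of the fully range-corrected
#' reconstruction.
#'
#' @inheritParams apply_pr_blur
#' @param mask optional logical array: compute the adjoint only at these
#'   voxels (others set to 0).  Used to restrict work to the image support
#'   during reconstruction.
#' @return [image_volume()].
#' @export
adjoint_pr_blur <- function(image, material_map, bank, mask = NULL) {
  pr_blur_impl(image, material_map, bank, adjoint = TRUE, mask = mask)
}

# memoise the homogeneity classification on the material map (it only
# depends on the labels and kernel size)
cache_homog <- function(material_map, kernel_size = 11L) {
  ks <- rep_len(as.integer(kernel_size), 3L)
  attr(material_map, "homog_cache") <-
    cpp_homog_map(map_labels0(material_map), dim(material_map$values),
                  (ks - 1L) %/% 2L)
  material_map
}

#' Kernel full width at half maximum
#'
#' FWHM of the central profile along one axis, by linear interpolation of
#' the half-maximum crossings.
#'
#' @param kernel a [pr_kernel()] (or any object with `$values` 3D array
#'   and `$voxel_size`).
#' @param axis profile axis (1, 2 or 3).
#' @return FWHM in mm.
#' @export
kernel_fwhm <- function(kernel, axis = 1L) {
  v <- kernel$values
  d <- dim(v)
  c0 <- (d + 1L) %/% 2L
  prof <- switch(axis,
                 v[, c0[2], c0[3]],
                 v[c0[1], , c0[3]],
                 v[c0[1], c0[2], ])
  profile_fwhm(prof, kernel$voxel_size[axis])
}

# linear-interpolated FWHM of a 1D profile sampled at uniform spacing
profile_fwhm <- function(prof, spacing) {
  n <- length(prof)
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  pk <- which.max(prof)
  half <- prof[pk] / 2
  cross <- function(idx_side) {
    # walk from the peak outward until the profile drops below half
    if (idx_side == "left") ii <- rev(seq_len(pk)) else ii <- pk:n
    below <- which(prof[ii] < half)
    if (!length(below)) return(x[ii[length(ii)]])  # never drops: edge
    b <- ii[below[1]]; a <- ii[below[1] - 1L]
    x[a] + (half - prof[a]) / (prof[b] - prof[a]) * (x[b] - x[a])
  }
  abs(cross("right") - cross("left"))
}

#' Serialize a kernel bank to JSON
#'
#' Stores kernel values, material specifications, isotope, event count and
#' seed in one JSON container; [read_kernel_bank()] restores it.
#'
#' @param bank a [build_kernel_bank()] result.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_kernel_bank <- function(bank, path) {
  obj <- list(
    isotope = bank$isotope, n_events = bank$n_events, seed = bank$seed,
    kernel_size = dim(bank$kernels[[1]]$values),
    voxel_size = bank$kernels[[1]]$voxel_size,
    materials = lapply(bank$materials, function(m)
      list(name = m$name, mass_density = m$mass_density,
           # stored as strings so that -Inf/Inf survive the JSON round trip
           hu_min = as.character(m$hu_min), hu_max = as.character(m$hu_max))),
    kernels = lapply(bank$kernels, function(k)
      list(values = as.numeric(k$values),
           discarded_fraction = k$discarded_fraction))
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a kernel bank from JSON
#'
#' @param path path written by [write_kernel_bank()].
#' @return A `kernel_bank`.
#' @export
read_kernel_bank <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ks <- as.integer(obj$kernel_size)
  # JSON Inf round-trips as character "Inf"
  num <- function(x) if (is.character(x)) as.numeric(x) else x
  materials <- lapply(obj$materials, function(m)
    material_spec(m$name, m$mass_density, num(m$hu_min), num(m$hu_max)))
  kernels <- lapply(names(obj$kernels), function(nm) {
    k <- obj$kernels[[nm]]
    pr_kernel(array(k$values, dim = ks), voxel_size = obj$voxel_size,
              material_tag = nm, discarded_fraction = k$discarded_fraction)
  })
  names(kernels) <- names(obj$kernels)
  structure(list(kernels = kernels, materials = materials,
                 isotope = obj$isotope, n_events = obj$n_events,
                 seed = obj$seed),
            class = "kernel_bank")
}
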