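# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

small_bank <- function() cached("small_bank", build_kernel_bank(
  n_events = 5e4, seed = 2))

# random two-material label map on an arbitrary grid
random_material_map <- function(dim, seed = 5, materials = c("lung", "soft")) {
  set.seed(seed)
  lab <- array(sample(seq_along(materials), prod(dim), replace = TRUE), dim)
  mm <- image_volume(lab, 2, "label")
  attr(mm$values, "materials") <- materials
  mm
}

uniform_material_map <- function(dim, material = "soft",
                                 materials = c("lung", "soft", "bone")) {
  lab <- array(match(material, materials), dim)
  mm <- image_volume(lab, 2, "label")
  attr(mm$values, "materials") <- materials
  mm
}

random_volume <- function(dim, seed = 1, voxel = 2) {
  set.seed(seed)
  image_volume(array(runif(prod(dim)), dim), voxel)
}

# independent R-level composition oracle: per-offset destination-material
# lookup with edge clamping, renormalized to unit sum
r_compose_kernel <- function(bank, material_map, idx) {
  d <- dim(material_map$values)
  levels <- attr(material_map$values, "materials")
  ks <- dim(bank$kernels[[1]]$values)
  half <- (ks - 1) / 2
  out <- array(0, ks)
  for (oz in -half[3]:half[3])
    for (oy in -half[2]:half[2])
      for (ox in -half[1]:half[1]) {
        j <- pmin(pmax(idx + c(ox, oy, oz), 1), d)
        m <- levels[material_map$values[j[1], j[2], j[3]]]
        out[ox + half[1] + 1, oy + half[2] + 1, oz + half[3] + 1] <-
          bank$kernels[[m]]$values[ox + half[1] + 1, oy + half[2] + 1,
                                   oz + half[3] + 1]
      }
  out / sum(out)
}

# independent dense shift-invariant convolution oracle (spread semantics,
# zero boundary): out[j] = sum_h k[h] x[j - h]
r_convolve <- function(x, kern) {
  d <- dim(x); ks <- dim(kern); half <- (ks - 1) / 2
  out <- array(0, d)
  for (oz in -half[3]:half[3])
    for (oy in -half[2]:half[2])
      for (ox in -half[1]:half[1]) {
        v <- kern[ox + half[1] + 1, oy + half[2] + 1, oz + half[3] + 1]
        if (v == 0) next
        sx <- max(1, 1 + ox):min(d[1], d[1] + ox)
        sy <- max(1, 1 + oy):min(d[2], d[2] + oy)
        sz <- max(1, 1 + oz):min(d[3], d[3] + oz)
        out[sx, sy, sz] <- out[sx, sy, sz] +
          v * x[sx - ox, sy - oy, sz - oz]
      }
  out
}

# small phantom + matched system model for reconstruction tests
toy_setup <- function(psf_fwhm = 4.4, with_pr = TRUE) {
  cached(sprintf("toy_setup_%g_%d", psf_fwhm, with_pr), {
    ph <- make_nema_iq(grid = c(48L, 48L, 12L), voxel_size = 2,
                       body_diameter = 80, sphere_diameters = c(10, 14),
                       sphere_ring_diameter = 40, n_background_vois = 4L,
                       background_voi_diameter = 14, voi_clearance = 2)
    mm <- segment_materials(ph$hu)
    geom <- scanner_geometry(c(48L, 48L, 12L), 2, n_angles = 24L)
    att <- attenuation_factors(hu_to_mu(ph$hu), geom)
    pr <- if (with_pr) list(bank = small_bank(), material_map = mm)
    model <- system_model(geom, attenuation = att, detector_fwhm = psf_fwhm,
                          pr = pr)
    list(phantom = ph, material_map = mm, geom = geom, model = model)
  })
}

# dense matrices of the factorized system model on a small grid:
# X (nLOR x J), per-LOR weights w, H_pr (J x J), H_det (J x J)
dense_toy <- function() {
  cached("dense_toy", {
    dims <- c(8L, 8L, 8L)
    J <- prod(dims)
    geom <- scanner_geometry(dims, 2, n_angles = 12L, n_radial = 10L)
    bank <- small_bank()
    set.seed(9)
    lab <- array(sample(1:3, J, replace = TRUE), dims)
    mm <- image_volume(lab, 2, "label")
    attr(mm$values, "materials") <- c("lung", "soft", "bone")
    mu <- image_volume(array(0.002 * runif(J), dims), 2, kind = "mu")
    att <- attenuation_factors(mu, geom)
    basis <- function(j) {
      v <- array(0, dims); v[j] <- 1
      image_volume(v, 2)
    }
    X <- vapply(seq_len(J), function(j)
      as.numeric(forward_project(basis(j), geom)$values),
      numeric(geom$n_radial * geom$n_angles * dims[3]))
    Hpr <- vapply(seq_len(J), function(j)
      as.numeric(apply_pr_blur(basis(j), mm, bank)$values), numeric(J))
    Hdet <- vapply(seq_len(J), function(j)
      as.numeric(detector_blur(basis(j), 4.4)$values), numeric(J))
    model <- system_model(geom, attenuation = att, detector_fwhm = 4.4,
                          pr = list(bank = bank, material_map = mm))
    list(dims = dims, geom = geom, model = model, bank = bank, mm = mm,
         X = X, w = as.numeric(att), Hpr = Hpr, Hdet = Hdet)
  })
}

# indices of the sinogram bins belonging to an angle subset
sino_subset_idx <- function(geom, subset) {
  arr <- array(seq_len(geom$n_radial * geom$n_angles * geom$image_dim[3]),
               dim = c(geom$n_radial, geom$n_angles, geom$image_dim[3]))
  as.numeric(arr[, subset, , drop = FALSE])
}

# explicit-matrix OSEM update (one full iteration over ordered subsets)
# for the three correction structures; mirrors the defining equations
dense_update <- function(dt, m, f0, prc_mode, psf_enabled, n_subsets = 4L,
                         eps) {
  geom <- dt$geom
  H <- diag(nrow(dt$Hpr))
  if (prc_mode != "none") H <- dt$Hpr
  if (psf_enabled) H <- dt$Hdet %*% H
  Hback <- if (prc_mode == "full" && psf_enabled) t(H)
  else if (prc_mode == "full") t(dt$Hpr)
  else if (psf_enabled) t(dt$Hdet)
  else diag(nrow(dt$Hpr))
  scheme <- partition_subsets(geom, n_subsets)
  f <- as.numeric(f0)
  mvec <- as.numeric(m)
  for (si in scheme$order) {
    sub <- scheme$subsets[[si]]
    rows <- sino_subset_idx(geom, sub)
    WX <- dt$w[rows] * dt$X[rows, , drop = FALSE]
    sens <- as.numeric(Hback %*% colSums(WX))
    y <- as.numeric(WX %*% (H %*% f))
    ratio <- mvec[rows] / (y + eps)
    corr <- as.numeric(Hback %*% crossprod(WX, ratio))
    upd <- sens > 0 & f > 0
    f[upd] <- f[upd] * corr[upd] / sens[upd]
  }
  f
}
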