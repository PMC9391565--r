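#' @name phantoms
#' @title Digital phantoms
#' @description
#' Digital activity/HU phantoms emulating the NEMA image-quality phantom,
#' a small-tumor variant with sub-centimetre spheres, and a bone-lung
#' phantom with cold tissue-mimicking cylinders carrying hot spheres.
#' Each generator returns a `phantom_set`: the activity volume (kBq/ml),
#' the CT volume (HU), the VOI protocol and the hot/background activity
#' ratio.  Spheres are voxelized with fractional sub-voxel sampling so
#' that sub-voxel-scale lesions carry partial-volume-correct activity;
#' cylinders and the body contour use the voxel-centre rule.
NULL

voi_row <- function(x, y, z, diameter, label) {
  data.frame(x = x, y = y, z = z, diameter = diameter, label = label,
             stringsAsFactors = FALSE)
}

#' VOI set
#'
#' @param sphere_vois data.frame with columns `x, y, z, diameter, label`
#'   (mm), one row per hot sphere.
#' @param background_vois same layout for the background VOIs.
#' @return An object of class `voi_set`.
#' @export
voi_set <- function(sphere_vois, background_vois) {
  for (i in seq_len(nrow(sphere_vois)))
    for (j in seq_len(nrow(background_vois))) {
      d <- sqrt(sum((unlist(sphere_vois[i, c("x", "y", "z")]) -
                       unlist(background_vois[j, c("x", "y", "z")]))^2))
      if (d < (sphere_vois$diameter[i] + background_vois$diameter[j]) / 2)
        stop(sprintf("background VOI %d overlaps sphere VOI %d", j, i))
    }
  structure(list(sphere_vois = sphere_vois,
                 background_vois = background_vois),
            class = "voi_set")
}

phantom_set <- function(activity, hu, vois, activity_ratio) {
  structure(list(activity = activity, hu = hu, vois = vois,
                 activity_ratio = activity_ratio),
            class = "phantom_set")
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> ratio %.3g, %d sphere VOIs, %d background VOIs\n",
              x$activity_ratio, nrow(x$vois$sphere_vois),
              nrow(x$vois$background_vois)))
  print(x$activity)
  invisible(x)
}

# fraction of each voxel (restricted to the sphere's bounding box) inside
# the sphere, by nsub^3 sub-voxel sampling; adds frac * delta to `arr`
add_sphere <- function(arr, xc, yc, zc, center, diameter, delta, nsub = 3L) {
  r <- diameter / 2
  vx <- c(xc[2] - xc[1], yc[2] - yc[1],
          if (length(zc) > 1) zc[2] - zc[1] else diameter)
  ix <- which(abs(xc - center[1]) <= r + vx[1])
  iy <- which(abs(yc - center[2]) <= r + vx[2])
  iz <- which(abs(zc - center[3]) <= r + vx[3])
  if (!length(ix) || !length(iy) || !length(iz))
    stop("sphere lies outside the grid")
  off <- (seq_len(nsub) - (nsub + 1) / 2) / nsub
  frac <- array(0, dim = c(length(ix), length(iy), length(iz)))
  for (oz in off) for (oy in off) for (ox in off) {
    dx2 <- outer(outer((xc[ix] + ox * vx[1] - center[1])^2,
                       (yc[iy] + oy * vx[2] - center[2])^2, "+"),
                 (zc[iz] + oz * vx[3] - center[3])^2, "+")
    frac <- frac + (dx2 <= r^2)
  }
  frac <- frac / nsub^3
  arr[ix, iy, iz] <- arr[ix, iy, iz] + frac * delta
  arr
}

# voxel-centre mask of an axial cylinder (infinite in z over `iz`)
cyl_mask2d <- function(xc, yc, center, diameter) {
  outer((xc - center[1])^2, (yc - center[2])^2, "+") <= (diameter / 2)^2
}

check_voi_inside_body <- function(vois, body_radius, half_z) {
  all_vois <- rbind(vois$sphere_vois, vois$background_vois)
  r_xy <- sqrt(all_vois$x^2 + all_vois$y^2) + all_vois$diameter / 2
  z_ext <- abs(all_vois$z) + all_vois$diameter / 2
  if (any(r_xy > body_radius) || any(z_ext > half_z))
    stop("VOI extends outside the phantom body: ",
         paste(all_vois$label[r_xy > body_radius | z_ext > half_z],
               collapse = ", "))
  invisible(TRUE)
}

build_body <- function(grid, voxel, body_diameter, background_activity,
                       body_hu = 0, outside_hu = -1000) {
  act <- array(0, dim = grid)
  hu <- array(outside_hu, dim = grid)
  tmp <- image_volume(act, voxel)
  xc <- voxel_centers(tmp, 1); yc <- voxel_centers(tmp, 2)
  zc <- voxel_centers(tmp, 3)
  body <- cyl_mask2d(xc, yc, c(0, 0), body_diameter)
  for (k in seq_along(zc)) {
    act[, , k][body] <- background_activity
    hu[, , k][body] <- body_hu
  }
  list(act = act, hu = hu, xc = xc, yc = yc, zc = zc, body = body)
}

#' NEMA image-quality phantom
#'
#' Cylindrical warm background (water HU, `background_activity`)
#' containing six hot spheres of 10/13/17/22/28/37 mm diameter, co-planar
#' in the central transaxial slice on a 114.4 mm diameter ring.  The VOI
#' protocol holds one VOI per sphere (diameter equal to the sphere
#' diameter) and twelve 37 mm background VOIs on a ring in the sphere
#' plane, clear of the spheres and of the body edge.
#'
#' @param grid integer grid dimensions, length 3.
#' @param voxel_size voxel size in mm.
#' @param sphere_activity,background_activity fill concentrations in
#'   kBq/ml (defaults 30 and 6, activity ratio 5).
#' @param sphere_diameters hot-sphere diameters in mm.
#' @param sphere_ring_diameter diameter of the ring carrying the sphere
#'   centres, mm.
#' @param body_diameter body cylinder diameter, mm.
#' @param n_background_vois,background_voi_diameter background VOI count
#'   and diameter (mm).
#' @param voi_clearance minimum clearance (mm) between a background VOI
#'   surface and both the sphere surfaces and the body edge.
#' @param subsamples sub-voxel sampling factor per axis for fractional
#'   sphere voxelization (1 = voxel-centre rule).
#' @return A `phantom_set`.
#' @export
make_nema_iq <- function(grid = c(160L, 160L, 24L), voxel_size = 2,
                         sphere_activity = 30, background_activity = 6,
                         sphere_diameters = c(10, 13, 17, 22, 28, 37),
                         sphere_ring_diameter = 114.4,
                         body_diameter = 286,
                         n_background_vois = 12L,
                         background_voi_diameter = 37,
                         voi_clearance = 15, subsamples = 3L) {
  fov <- grid[1:2] * rep_len(voxel_size, 3)[1:2]
  if (body_diameter > min(fov))
    stop("grid too small for the body cylinder")
  b <- build_body(grid, voxel_size, body_diameter, background_activity)
  ang <- (seq_along(sphere_diameters) - 1L) * 2 * pi / length(sphere_diameters)
  sx <- sphere_ring_diameter / 2 * cos(ang)
  sy <- sphere_ring_diameter / 2 * sin(ang)
  act <- b$act
  for (i in seq_along(sphere_diameters)) {
    if (sphere_ring_diameter / 2 + sphere_diameters[i] / 2 > body_diameter / 2)
      stop(sprintf("sphere %g mm does not fit inside the body",
                   sphere_diameters[i]))
    act <- add_sphere(act, b$xc, b$yc, b$zc, c(sx[i], sy[i], 0),
                      sphere_diameters[i],
                      sphere_activity - background_activity,
                      nsub = subsamples)
  }
  svois <- voi_row(sx, sy, 0, sphere_diameters,
                   sprintf("sphere_%gmm", sphere_diameters))
  bg_ring <- body_diameter / 2 - background_voi_diameter / 2 - voi_clearance
  bang <- (seq_len(n_background_vois) - 0.5) * 2 * pi / n_background_vois
  bvois <- voi_row(bg_ring * cos(bang), bg_ring * sin(bang), 0,
                   background_voi_diameter,
                   sprintf("background_%02d", seq_len(n_background_vois)))
  vois <- voi_set(svois, bvois)
  half_z <- grid[3] * rep_len(voxel_size, 3)[3] / 2
  check_voi_inside_body(vois, body_diameter / 2, half_z)
  phantom_set(image_volume(act, voxel_size, "activity"),
              image_volume(b$hu, voxel_size, "hu"),
              vois, sphere_activity / background_activity)
}

#' Small-tumor phantom
#'
#' Same housing as [make_nema_iq()] but with six sub-centimetre hot
#' spheres (3.7-9.7 mm) at 25 kBq/ml in a 1.2 kBq/ml background
#' (20.8:1 ratio), and ten 20 mm background VOIs.  Spheres are laid out
#' on a ring in the central transaxial plane.
#'
#' @inheritParams make_nema_iq
#' @return A `phantom_set`.
#' @export
make_small_tumor <- function(grid = c(160L, 160L, 24L), voxel_size = 2,
                             sphere_activity = 25, background_activity = 1.2,
                             sphere_diameters = c(3.7, 4.8, 6.5, 7.7, 8.9, 9.7),
                             sphere_ring_diameter = 114.4,
                             body_diameter = 286,
                             n_background_vois = 10L,
                             background_voi_diameter = 20,
                             voi_clearance = 15, subsamples = 3L) {
  make_nema_iq(grid = grid, voxel_size = voxel_size,
               sphere_activity = sphere_activity,
               background_activity = background_activity,
               sphere_diameters = sphere_diameters,
               sphere_ring_diameter = sphere_ring_diameter,
               body_diameter = body_diameter,
               n_background_vois = n_background_vois,
               background_voi_diameter = background_voi_diameter,
               voi_clearance = voi_clearance, subsamples = subsamples)
}

#' Bone-lung phantom
#'
#' Water background (6 kBq/ml) holding three cold 50 mm cylinders of lung
#' (-800 HU), bone (500 HU) and dense bone (1000 HU), each carrying two
#' hot water-filled spheres (8.5 and 19.4 mm, 30 kBq/ml).  Cylinders run
#' the full axial extent; spheres sit in the central transaxial plane.
#' Six 37 mm background VOIs are placed in the water background.
#'
#' @inheritParams make_nema_iq
#' @param cylinder_diameter cold cylinder diameter, mm.
#' @param cylinder_hu HU of the three cylinders.
#' @param cylinder_ring_diameter diameter of the ring carrying the
#'   cylinder axes, mm.
#' @return A `phantom_set`.
#' @export
make_bone_lung <- function(grid = c(160L, 160L, 24L), voxel_size = 2,
                           sphere_activity = 30, background_activity = 6,
                           sphere_diameters = c(8.5, 19.4),
                           cylinder_diameter = 50,
                           cylinder_hu = c(lung = -800, bone500 = 500,
                                           bone1000 = 1000),
                           cylinder_ring_diameter = 120,
                           body_diameter = 286,
                           n_background_vois = 6L,
                           background_voi_diameter = 37,
                           voi_clearance = 15, subsamples = 3L) {
  fov <- grid[1:2] * rep_len(voxel_size, 3)[1:2]
  if (body_diameter > min(fov))
    stop("grid too small for the body cylinder")
  if (cylinder_ring_diameter / 2 + cylinder_diameter / 2 > body_diameter / 2)
    stop("cylinders do not fit inside the body")
  b <- build_body(grid, voxel_size, body_diameter, background_activity)
  act <- b$act; hu <- b$hu
  cang <- c(90, 210, 330) * pi / 180
  cx <- cylinder_ring_diameter / 2 * cos(cang)
  cy <- cylinder_ring_diameter / 2 * sin(cang)
  svois <- NULL
  # local in-cylinder sphere offsets along the radial direction
  local_off <- c(-7, 9)
  for (ci in seq_along(cang)) {
    cylm <- cyl_mask2d(b$xc, b$yc, c(cx[ci], cy[ci]), cylinder_diameter)
    for (k in seq_along(b$zc)) {
      act[, , k][cylm] <- 0          # cold cylinder
      hu[, , k][cylm] <- cylinder_hu[ci]
    }
    u <- c(cos(cang[ci]), sin(cang[ci]))
    for (si in seq_along(sphere_diameters)) {
      ctr <- c(cx[ci] + local_off[si] * u[1],
               cy[ci] + local_off[si] * u[2], 0)
      if (abs(local_off[si]) + sphere_diameters[si] / 2 >
            cylinder_diameter / 2)
        stop("sphere does not fit inside its cylinder")
      # spheres are water-filled: restore water HU inside the sphere
      act <- add_sphere(act, b$xc, b$yc, b$zc, ctr, sphere_diameters[si],
                        sphere_activity, nsub = subsamples)
      kz <- which(abs(b$zc - ctr[3]) <= sphere_diameters[si] / 2)
      for (k in kz) {
        zoff <- b$zc[k] - ctr[3]
        r2d <- sqrt(max((sphere_diameters[si] / 2)^2 - zoff^2, 0))
        m <- cyl_mask2d(b$xc, b$yc, ctr[1:2], 2 * r2d)
        hu[, , k][m] <- 0
      }
      svois <- rbind(svois, voi_row(ctr[1], ctr[2], ctr[3],
                                    sphere_diameters[si],
                                    sprintf("%s_%gmm", names(cylinder_hu)[ci],
                                            sphere_diameters[si])))
    }
  }
  bg_ring <- body_diameter / 2 - background_voi_diameter / 2 - voi_clearance
  bang <- (seq_len(n_background_vois) - 1L) * 2 * pi / n_background_vois
  bvois <- voi_row(bg_ring * cos(bang), bg_ring * sin(bang), 0,
                   background_voi_diameter,
                   sprintf("background_%02d", seq_len(n_background_vois)))
  # keep background VOIs out of the cold cylinders
  for (j in seq_len(nrow(bvois))) {
    d <- sqrt((bvois$x[j] - cx)^2 + (bvois$y[j] - cy)^2)
    if (any(d < (background_voi_diameter + cylinder_diameter) / 2))
      stop("background VOI overlaps a cold cylinder; adjust geometry")
  }
  vois <- voi_set(svois, bvois)
  half_z <- grid[3] * rep_len(voxel_size, 3)[3] / 2
  check_voi_inside_body(vois, body_diameter / 2, half_z)
  phantom_set(image_volume(act, voxel_size, "activity"),
              image_volume(hu, voxel_size, "hu"),
              vois, sphere_activity / background_activity)
}

#' Segment a CT volume into material labels
#'
#' Labels every voxel by the HU interval of the material set.  Air falls
#' in the lung interval by construction of [default_materials()] (air is
#' treated as lung for positron-range purposes: both are low-density
#' media in which positrons travel far).
#'
#' @param hu HU [image_volume()].
#' @param materials named list of [material_spec()]s partitioning the HU
#'   axis.
#' @return Label [image_volume()] with integer values indexing
#'   `materials`; the level names are kept in the `"materials"` attribute
#'   of `$values`.
#' @export
segment_materials <- function(hu, materials = default_materials()) {
  validate_materials(materials)
  ord <- order(vapply(materials, function(m) m$hu_min, numeric(1)))
  breaks <- c(-Inf, vapply(materials[ord], function(m) m$hu_max, numeric(1)))
  lab <- array(as.integer(cut(hu$values, breaks = breaks, labels = FALSE)),
               dim = dim(hu$values))
  # map back to the original material order
  remap <- match(seq_along(materials), ord)
  lab <- array(remap[lab], dim = dim(hu$values))
  out <- image_volume(lab, hu$voxel_size, "label")
  attr(out$values, "materials") <- names(materials)
  out
}

#' Convert HU to 511 keV linear attenuation
#'
#' Piecewise-linear (bilinear) conversion anchored at
#' `mu(air, -1000 HU) = 0` and `mu(water, 0 HU) = 0.0096/mm`; above 0 HU
#' the slope follows the bone anchor `mu(1000 HU) = 0.0172/mm` (cortical
#' bone at 511 keV), i.e. 7.6e-6 per HU.  Negative results are clamped
#' to 0.
#'
#' @param hu HU [image_volume()].
#' @return Attenuation [image_volume()] in 1/mm.
#' @export
hu_to_mu <- function(hu) {
  mu_water <- 0.0096
  slope_hi <- (0.0172 - mu_water) / 1000
  v <- hu$values
  mu <- ifelse(v <= 0, mu_water * (1 + v / 1000), mu_water + slope_hi * v)
  mu <- pmax(mu, 0)
  vol_like(hu, mu, kind = "mu")
}
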