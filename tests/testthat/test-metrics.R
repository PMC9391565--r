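# hand-built 5x5x5 toy: two sphere-VOI voxels at 8, four background
# voxels at 2 -> CR = (8/2)/5 = 0.8
toy_metric_image <- function() {
  img <- image_volume(array(2, c(5, 5, 5)), voxel_size = 1)
  img$values[2, 3, 3] <- 8
  img$values[3, 3, 3] <- 8
  img
}

toy_metric_vois <- function() {
  sv <- data.frame(x = -0.5, y = 0, z = 0, diameter = 2.2, label = "toy")
  bv <- data.frame(x = c(2, -2, 2, -2), y = c(2, 2, -2, -2), z = 0,
                   diameter = 0.9,
                   label = sprintf("bg%d", 1:4))
  voi_set(sv, bv)
}

test_that("contrast recovery reproduces the arithmetic worked example", {
  cr <- contrast_recovery(toy_metric_image(), toy_metric_vois(),
                          activity_ratio = 5)
  expect_equal(unname(cr), 0.8)
  expect_named(cr, "toy")
})

test_that("contrast recovery is exactly 1 on a centre-rule ground truth", {
  ph <- cached("nema_center_rule",
               make_nema_iq(grid = c(96L, 96L, 16L), body_diameter = 180,
                            sphere_ring_diameter = 60,
                            sphere_diameters = c(10, 17, 28),
                            n_background_vois = 6L,
                            background_voi_diameter = 20,
                            voi_clearance = 4, subsamples = 1L))
  cr <- contrast_recovery(ph$activity, ph$vois, ph$activity_ratio)
  expect_equal(unname(cr), rep(1, 3))
  # zero-contrast limit: flat image scores 1 / ratio
  flat <- ph$activity
  flat$values[] <- 6
  expect_equal(unname(contrast_recovery(flat, ph$vois, 5)), rep(0.2, 3))
})

test_that("background noise is the population CV in percent", {
  img <- image_volume(array(5, c(5, 5, 5)), voxel_size = 1)
  img$values[2, 3, 3] <- 4
  img$values[4, 3, 3] <- 6
  bv <- data.frame(x = c(-1, 1), y = 0, z = 0, diameter = 0.9,
                   label = c("a", "b"))
  expect_equal(image_noise(img, bv), 20)   # values {4, 6}: SD 1, mean 5
  flat <- image_volume(array(7, c(5, 5, 5)), 1)
  expect_equal(image_noise(flat, bv), 0)
})

test_that("CR and noise are invariant under global positive scaling", {
  img <- toy_metric_image()
  vois <- toy_metric_vois()
  set.seed(3)
  img$values <- img$values * (1 + 0.1 * runif(length(img$values)))
  for (c0 in c(0.2, 7)) {
    scaled <- img; scaled$values <- scaled$values * c0
    expect_equal(contrast_recovery(scaled, vois, 5),
                 contrast_recovery(img, vois, 5), tolerance = 1e-12)
    expect_equal(image_noise(scaled, vois$background_vois),
                 image_noise(img, vois$background_vois), tolerance = 1e-12)
  }
})

test_that("empty VOIs and zero background are reported as errors", {
  img <- image_volume(array(0, c(5, 5, 5)), 1)
  bv <- data.frame(x = 0, y = 0, z = 0, diameter = 0.9, label = "bg")
  expect_error(image_noise(img, bv), "zero background")
  sv <- data.frame(x = 10, y = 0, z = 0, diameter = 0.5, label = "gone")
  img$values[] <- 1
  expect_error(contrast_recovery(img, structure(
    list(sphere_vois = sv, background_vois = bv), class = "voi_set"), 5),
    "gone")
})

test_that("matched-noise iteration selection is the nearest-noise argmin", {
  tab <- data.frame(variant = "v", iteration = rep(1:3, each = 2),
                    sphere = rep(c("a", "b"), 3),
                    contrast_recovery = 0.5,
                    noise_pct = rep(c(6, 9.7, 13), each = 2))
  sel <- select_iteration_at_noise(tab, 10)
  expect_equal(sel$iteration, 2L)
  expect_false(sel$unreachable)
  # tie -> lower iteration
  tab2 <- data.frame(variant = "v", iteration = 1:2, sphere = "a",
                     contrast_recovery = 0.5, noise_pct = c(10, 10))
  expect_equal(select_iteration_at_noise(tab2, 10)$iteration, 1L)
  # unreachable flag when noise never gets within 5 points of the target
  tab3 <- data.frame(variant = "v", iteration = 1:3, sphere = "a",
                     contrast_recovery = 0.5, noise_pct = c(1, 2, 3))
  expect_true(select_iteration_at_noise(tab3, 10)$unreachable)
  # exhaustive-oracle property on a monotone sequence crossing the target
  noise <- c(2, 5, 8.2, 11.5, 16, 22)
  tab4 <- data.frame(variant = "v", iteration = 1:6, sphere = "a",
                     contrast_recovery = 0.5, noise_pct = noise)
  expect_equal(select_iteration_at_noise(tab4, 10)$iteration,
               which.min(abs(noise - 10)))
})

test_that("convergence table holds one row per variant, iteration and sphere", {
  ts <- toy_setup()
  proj <- simulate_acquisition(ts$phantom, ts$model, 1e5, seed = 6)
  res <- run_variant_suite(proj, ts$model, variants = c("OSEM", "PSF"),
                           n_subsets = 4L,
                           n_iterations = c(OSEM = 3L, PSF = 3L))
  ev <- convergence_table(res, ts$phantom$vois, ts$phantom$activity_ratio)
  tab <- ev$per_iteration
  expect_equal(nrow(tab), 2 * 3 * 2)   # 2 variants x 3 iterations x 2 spheres
  expect_setequal(unique(tab$variant), c("OSEM", "PSF"))
  # determinism: identical inputs give identical rows
  ev2 <- convergence_table(res, ts$phantom$vois, ts$phantom$activity_ratio)
  expect_identical(tab, ev2$per_iteration)
  # missing iterates are an error
  res$OSEM$iterates <- NULL
  expect_error(convergence_table(res, ts$phantom$vois, 5), "iterates")
})

test_that("largest-sphere contrast is non-decreasing on noiseless data", {
  ts <- toy_setup()
  pnl <- simulate_acquisition(ts$phantom, ts$model, 1e6, noiseless = TRUE)
  res <- run_variant_suite(pnl, ts$model, variants = "PSF+PRC",
                           n_subsets = 4L, n_iterations = c("PSF+PRC" = 6L))
  ev <- convergence_table(res, ts$phantom$vois, ts$phantom$activity_ratio)
  big <- ev$per_iteration[ev$per_iteration$sphere == "sphere_14mm", ]
  expect_true(all(diff(big$contrast_recovery) > -1e-9))
})

test_that("edge overshoot detects a synthetic rim and nothing on truth", {
  ph <- cached("nema_center_rule",
               make_nema_iq(grid = c(96L, 96L, 16L), body_diameter = 180,
                            sphere_ring_diameter = 60,
                            sphere_diameters = c(10, 17, 28),
                            n_background_vois = 6L,
                            background_voi_diameter = 20,
                            voi_clearance = 4, subsamples = 1L))
  sv <- ph$vois$sphere_vois[ph$vois$sphere_vois$diameter == 28, ]
  ctr <- c(sv$x, sv$y, sv$z)
  expect_equal(edge_overshoot(ph$activity, ctr, 28, 30, 6), 0)
  # add an 8% rim annulus just inside the sphere boundary
  rim <- ph$activity
  xc <- voxel_centers(rim, 1)
  yc <- voxel_centers(rim, 2)
  iz <- which.min(abs(voxel_centers(rim, 3) - ctr[3]))
  rho <- sqrt(outer((xc - ctr[1])^2, (yc - ctr[2])^2, "+"))
  ann <- rho <= 13 & rho > 7
  pl <- rim$values[, , iz]
  pl[ann] <- 30 * 1.08
  rim$values[, , iz] <- pl
  expect_equal(edge_overshoot(rim, ctr, 28, 30, 6), 8, tolerance = 0.01)
  # invariant to joint scaling of image and reference activities
  rim2 <- rim; rim2$values <- rim2$values * 3.7
  expect_equal(edge_overshoot(rim2, ctr, 28, 30 * 3.7, 6 * 3.7),
               edge_overshoot(rim, ctr, 28, 30, 6), tolerance = 1e-12)
  expect_error(edge_overshoot(rim, ctr, 28, 5, 6), "degenerate")
})
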