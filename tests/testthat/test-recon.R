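test_that("every variant's update matches the explicit-matrix evaluation", {
  dt <- dense_toy()
  geom <- dt$geom
  # self-consistent noisy-ish data from the dense model
  set.seed(21)
  f_true <- as.numeric(random_volume(dt$dims, seed = 21)$values) + 0.1
  H_full <- dt$Hdet %*% dt$Hpr
  m <- array(dt$w * as.numeric(dt$X %*% (H_full %*% f_true)),
             c(geom$n_radial, geom$n_angles, dt$dims[3]))
  m <- m / mean(m) * 5
  proj <- structure(list(values = m, geometry = geom, angle_idx = NULL,
                         is_noisy = FALSE), class = "projection_data")
  init <- image_volume(array(1, dt$dims), 2)
  eps <- 1e-12 * mean(m)
  tab <- prc_variants()
  for (i in seq_len(nrow(tab))) {
    cfg <- recon_config(n_iterations = 1L, n_subsets = 4L,
                        prc_mode = tab$prc_mode[i],
                        psf_enabled = tab$psf_enabled[i],
                        initial_image = init)
    got <- reconstruct(proj, dt$model, cfg)$final_image
    want <- dense_update(dt, m, array(1, dt$dims), tab$prc_mode[i],
                         tab$psf_enabled[i], n_subsets = 4L, eps = eps)
    expect_equal(as.numeric(got$values), want, tolerance = 1e-8,
                 info = tab$variant[i])
  }
})

test_that("simplified-mode sensitivity is identical to the uncorrected one", {
  dt <- dense_toy()
  scheme <- partition_subsets(dt$geom, 4L)
  for (sub in scheme$subsets[1:2]) {
    s_none <- sensitivity_image(dt$model, sub, "none", psf_enabled = FALSE)
    s_simp <- sensitivity_image(dt$model, sub, "simplified",
                                psf_enabled = FALSE)
    expect_identical(s_none$values, s_simp$values)
  }
})

test_that("full-mode sensitivity matches the dense-matrix denominator", {
  dt <- dense_toy()
  scheme <- partition_subsets(dt$geom, 4L)
  sub <- scheme$subsets[[1]]
  rows <- sino_subset_idx(dt$geom, sub)
  WX <- dt$w[rows] * dt$X[rows, , drop = FALSE]
  want <- as.numeric(t(dt$Hdet %*% dt$Hpr) %*% colSums(WX))
  got <- sensitivity_image(dt$model, sub, "full", psf_enabled = TRUE)
  expect_equal(as.numeric(got$values), want, tolerance = 1e-10)
  expect_error(sensitivity_image(dt$model, integer(0), "full"), "empty")
})

test_that("MLEM keeps the Poisson log-likelihood non-decreasing", {
  ts <- toy_setup()
  proj <- simulate_acquisition(ts$phantom, ts$model, 2e5, seed = 3)
  cfg <- recon_config(n_iterations = 20L, n_subsets = 1L,
                      prc_mode = "none", psf_enabled = FALSE,
                      keep_iterates = TRUE)
  res <- reconstruct(proj, ts$model, cfg)
  att <- ts$model$attenuation
  ll <- vapply(res$iterates, function(img) {
    y <- forward_project(img, ts$geom)$values * att
    sum(proj$values * log(y + 1e-300) - y)
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-8 * abs(ll[-1])))
})

test_that("matched projector pairs are a fixed point of their own data", {
  ts <- toy_setup()
  sims <- list(
    none = system_model(ts$geom, attenuation = ts$model$attenuation),
    psf  = system_model(ts$geom, attenuation = ts$model$attenuation,
                        detector_fwhm = 4.4),
    full = ts$model
  )
  modes <- list(none = c("none", FALSE), psf = c("none", TRUE),
                full = c("full", TRUE))
  for (nm in names(sims)) {
    model <- sims[[nm]]
    pnl <- simulate_acquisition(ts$phantom, model, 1e6, noiseless = TRUE)
    truth <- ts$phantom$activity
    truth$values <- truth$values * attr(pnl, "count_scale")
    cfg <- recon_config(n_iterations = 1L, n_subsets = 4L,
                        prc_mode = modes[[nm]][1],
                        psf_enabled = as.logical(modes[[nm]][2]),
                        initial_image = truth)
    res <- reconstruct(pnl, model, cfg)
    expect_lt(max(abs(c(res$log$mult_min, res$log$mult_max) - 1)), 1e-6)
  }
})

test_that("iterates stay non-negative and no clipping occurs", {
  ts <- toy_setup()
  proj <- simulate_acquisition(ts$phantom, ts$model, 1e5, seed = 5)
  cfg <- recon_config(n_iterations = 3L, n_subsets = 4L, prc_mode = "full",
                      psf_enabled = TRUE, keep_iterates = TRUE)
  res <- reconstruct(proj, ts$model, cfg)
  expect_true(all(res$final_image$values >= 0))
  expect_true(all(res$log$clips == 0L))
  expect_length(res$iterates, 3L)
})

test_that("variant names map to the documented correction settings", {
  tab <- prc_variants()
  expect_equal(tab$prc_mode[tab$variant == "OSEM"], "none")
  expect_false(tab$psf_enabled[tab$variant == "OSEM"])
  expect_equal(tab$prc_mode[tab$variant == "PSF+PRC"], "full")
  expect_true(tab$psf_enabled[tab$variant == "PSF+PRC"])
  expect_equal(tab$n_iterations[tab$variant == "PSF+PRC"], 20L)
  expect_error(run_variant_suite(NULL, NULL, variants = "OSEM+MAGIC"),
               "unknown")
})

test_that("the variant suite returns one result per variant with its iterates", {
  ts <- toy_setup()
  proj <- simulate_acquisition(ts$phantom, ts$model, 1e5, seed = 6)
  res <- run_variant_suite(proj, ts$model,
                           variants = c("OSEM", "OSEM+PRC simplified",
                                        "PSF+PRC"),
                           n_subsets = 4L,
                           n_iterations = c("OSEM" = 2L,
                                            "OSEM+PRC simplified" = 2L,
                                            "PSF+PRC" = 3L))
  expect_named(res, c("OSEM", "OSEM+PRC simplified", "PSF+PRC"))
  expect_length(res$OSEM$iterates, 2L)
  expect_length(res$`PSF+PRC`$iterates, 3L)
  expect_equal(res$`PSF+PRC`$config$prc_mode, "full")
})

test_that("requesting range correction without kernels is an error", {
  ts <- toy_setup()
  plain <- system_model(ts$geom, attenuation = ts$model$attenuation)
  proj <- simulate_acquisition(ts$phantom, plain, 1e4, noiseless = TRUE)
  cfg <- recon_config(n_iterations = 1L, n_subsets = 4L, prc_mode = "full")
  expect_error(reconstruct(proj, plain, cfg), "kernels")
})
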