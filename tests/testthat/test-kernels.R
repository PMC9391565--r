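test_that("a zero-energy spectrum produces a delta kernel", {
  sp <- positron_spectrum(0, 0.5, "degenerate")
  mat <- material_spec("soft", 1.0, -150, 150)
  k <- build_uniform_kernel(sp, mat, n_events = 1000, seed = 1)
  expect_equal(k$values[6, 6, 6], 1)
  expect_equal(sum(k$values), 1)
  expect_equal(sum(k$values != 0), 1L)
})

test_that("kernels are unit-sum and symmetric within Monte-Carlo error", {
  bank <- small_bank()
  for (k in bank$kernels) {
    v <- k$values
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
    flipped <- v[11:1, 11:1, 11:1]
    # z-score of each point-symmetric bin pair under binomial error
    n <- bank$n_events * (1 - k$discarded_fraction)
    p <- (v + flipped) / 2
    z <- abs(v - flipped) / sqrt(pmax(2 * p / n, 1e-12))
    expect_lt(max(z[p > 0]), 5)
    expect_true(all(v[p == 0] == 0))
  }
})

test_that("even kernel sizes are rejected", {
  sp <- i124_positron_spectrum()
  mat <- material_spec("soft", 1.0, -150, 150)
  expect_error(build_uniform_kernel(sp, mat, kernel_size = 10L), "odd")
  expect_error(pr_kernel(array(1, c(4, 5, 5)), 2), "odd")
})

test_that("kernel FWHM decreases with material density", {
  bank <- cached("bank_1e5", build_kernel_bank(n_events = 1e5, seed = 3))
  f <- vapply(bank$kernels, kernel_fwhm, numeric(1))
  expect_gt(f[["lung"]], f[["soft"]])
  expect_gt(f[["soft"]], f[["bone"]])
})

test_that("composition on a uniform map reproduces the material kernel", {
  bank <- small_bank()
  for (m in c("soft", "lung")) {
    mm <- uniform_material_map(c(24L, 24L, 24L), m)
    k <- compose_voxel_kernel(bank, mm, c(12, 12, 12))
    expect_equal(k$values, bank$kernels[[m]]$values, tolerance = 1e-12)
  }
})

test_that("composition at an interface matches the brute-force lookup", {
  bank <- small_bank()
  # 3-voxel-thick lung slab inside soft tissue
  lab <- array(2L, c(24L, 24L, 24L))
  lab[11:13, , ] <- 1L
  mm <- image_volume(lab, 2, "label")
  attr(mm$values, "materials") <- c("lung", "soft")
  for (idx in list(c(12, 12, 12), c(10, 12, 12), c(14, 8, 12),
                   c(2, 2, 2))) {   # includes an edge-clamped voxel
    k <- compose_voxel_kernel(bank, mm, idx)
    expect_equal(k$values, r_compose_kernel(bank, mm, idx),
                 tolerance = 1e-12)
  }
  # a label missing from the bank is reported by name
  attr(mm$values, "materials") <- c("plastic", "soft")
  expect_error(compose_voxel_kernel(bank, mm, c(12, 12, 12)), "plastic")
})

test_that("blurring a delta spreads the composed kernel around it", {
  bank <- small_bank()
  mm <- random_material_map(c(20L, 20L, 20L), seed = 8)
  x <- image_volume(array(0, c(20L, 20L, 20L)), 2)
  x$values[10, 9, 11] <- 2.5
  out <- apply_pr_blur(x, mm, bank)
  k <- compose_voxel_kernel(bank, mm, c(10, 9, 11))
  expect_equal(out$values[5:15, 4:14, 6:16], 2.5 * k$values,
               tolerance = 1e-12)
})

test_that("uniform-map blur equals dense shift-invariant convolution", {
  bank <- small_bank()
  dims <- c(32L, 32L, 16L)
  mm <- uniform_material_map(dims, "soft")
  x <- random_volume(dims, seed = 3)
  out <- apply_pr_blur(x, mm, bank)
  oracle <- r_convolve(x$values, bank$kernels$soft$values)
  expect_equal(out$values, oracle, tolerance = 1e-10)
  # the adjoint is the correlation, i.e. convolution with the flipped kernel
  adj <- adjoint_pr_blur(x, mm, bank)
  oracle_adj <- r_convolve(x$values,
                           bank$kernels$soft$values[11:1, 11:1, 11:1])
  expect_equal(adj$values, oracle_adj, tolerance = 1e-10)
  # with an exactly symmetric kernel the operator is self-adjoint
  sym_bank <- bank
  ks <- bank$kernels$soft$values
  sym_bank$kernels$soft$values <- (ks + ks[11:1, 11:1, 11:1]) / 2
  adj2 <- adjoint_pr_blur(x, mm, sym_bank)
  fwd2 <- apply_pr_blur(x, mm, sym_bank)
  expect_equal(adj2$values, fwd2$values, tolerance = 1e-12)
})

test_that("blur conserves mass for interior-supported images", {
  bank <- small_bank()
  dims <- c(24L, 24L, 24L)
  mm <- random_material_map(dims, seed = 4)
  x <- image_volume(array(0, dims), 2)
  set.seed(6)
  x$values[7:18, 7:18, 7:18] <- runif(12^3)
  out <- apply_pr_blur(x, mm, bank)
  expect_equal(sum(out$values), sum(x$values), tolerance = 1e-6)
  expect_true(all(out$values >= 0))
})

test_that("forward and adjoint blur pass the inner-product test", {
  bank <- small_bank()
  dims <- c(16L, 16L, 16L)
  mm <- random_material_map(dims, seed = 5)
  x <- random_volume(dims, seed = 1)
  y <- random_volume(dims, seed = 2)
  lhs <- sum(apply_pr_blur(x, mm, bank)$values * y$values)
  rhs <- sum(x$values * adjoint_pr_blur(y, mm, bank)$values)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
})

test_that("adjoint blur of a delta matches the explicit transpose", {
  bank <- small_bank()
  dims <- c(12L, 12L, 12L)
  mm <- random_material_map(dims, seed = 12)
  y <- image_volume(array(0, dims), 2)
  y$values[6, 6, 6] <- 1
  adj <- adjoint_pr_blur(y, mm, bank)
  # brute force: z[k] = rho_k(j - k) for j the delta location
  half <- 5L
  for (k in list(c(6, 6, 6), c(4, 7, 6), c(9, 3, 8))) {
    off <- c(6, 6, 6) - k
    rho <- r_compose_kernel(bank, mm, k)
    expect_equal(adj$values[k[1], k[2], k[3]],
                 rho[off[1] + half + 1, off[2] + half + 1,
                     off[3] + half + 1],
                 tolerance = 1e-12)
  }
})

test_that("grid mismatch between image and material map is an error", {
  bank <- small_bank()
  mm <- uniform_material_map(c(16L, 16L, 16L))
  x <- random_volume(c(16L, 16L, 8L))
  expect_error(apply_pr_blur(x, mm, bank), "grid")
})

test_that("kernel banks round-trip through JSON serialization", {
  bank <- small_bank()
  path <- tempfile(fileext = ".json")
  write_kernel_bank(bank, path)
  back <- read_kernel_bank(path)
  expect_equal(names(back$kernels), names(bank$kernels))
  for (m in names(bank$kernels))
    expect_equal(back$kernels[[m]]$values, bank$kernels[[m]]$values)
  expect_equal(back$materials$lung$hu_min, -Inf)
  expect_equal(back$seed, bank$seed)
  unlink(path)
})
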