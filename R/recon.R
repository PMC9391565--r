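#' Reconstruction configuration
#'
#' @param n_iterations number of full passes over all subsets.
#' @param n_subsets number of angular subsets (1 = MLEM).
#' @param prc_mode positron-range correction mode: `"none"`,
#'   `"simplified"` (range blur before the forward projection only, with
#'   the back projector and sensitivity image left unchanged) or
#'   `"full"` (range blur and its exact adjoint in forward and back
#'   projection and in the sensitivity image).
#' @param psf_enabled include the detector PSF in the system model's
#'   resolution factor (forward, backward and sensitivity).
#' @param keep_iterates keep the image after every full iteration.
#' @param epsilon_scale the division guard added to projected
#'   denominators is `epsilon_scale * mean(measured data)`.
#' @param initial_image optional starting [image_volume()]; default is a
#'   uniform positive image inside the FOV cylinder.
#' @param fov_radius_mm radius of the initialization cylinder (default:
#'   the radial FOV).  Voxels outside start at zero and stay zero under
#'   the multiplicative update, restricting work to the supported region.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 10L, n_subsets = 12L,
                         prc_mode = c("none", "simplified", "full"),
                         psf_enabled = FALSE, keep_iterates = FALSE,
                         epsilon_scale = 1e-12, initial_image = NULL,
                         fov_radius_mm = NULL) {
  prc_mode <- match.arg(prc_mode)
  if (n_iterations < 1) stop("`n_iterations` must be >= 1")
  if (epsilon_scale <= 0) stop("`epsilon_scale` must be > 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets), prc_mode = prc_mode,
                 psf_enabled = isTRUE(psf_enabled),
                 keep_iterates = isTRUE(keep_iterates),
                 epsilon_scale = epsilon_scale,
                 initial_image = initial_image,
                 fov_radius_mm = fov_radius_mm),
            class = "recon_config")
}

# adjoint of the resolution factor H used in the back step / sensitivity.
# PR adjoint enters only in full mode; the detector blur is self-adjoint.
apply_h_adjoint <- function(img, model, prc_mode, psf_enabled, mask = NULL) {
  if (psf_enabled && model$detector_fwhm > 0)
    img <- detector_blur(img, model$detector_fwhm)
  if (prc_mode == "full")
    img <- adjoint_pr_blur(img, model$pr$material_map, model$pr$bank,
                           mask = mask)
  img
}

apply_h_forward <- function(img, model, prc_mode, psf_enabled) {
  if (prc_mode != "none")
    img <- apply_pr_blur(img, model$pr$material_map, model$pr$bank)
  if (psf_enabled && model$detector_fwhm > 0)
    img <- detector_blur(img, model$detector_fwhm)
  img
}

#' Per-subset sensitivity image
#'
#' The OSEM update denominator: the back projection of the subset's
#' per-LOR weights, with the adjoint of the resolution factor applied
#' according to the correction mode.  The simplified range correction
#' leaves the denominator identical to the uncorrected one by
#' construction; only the full mode adds the range-kernel adjoint.
#'
#' @param model a [system_model()].
#' @param subset 1-based angle indices of the subset.
#' @param prc_mode,psf_enabled see [recon_config()].
#' @param mask optional logical array restricting the range-adjoint work.
#' @return Sensitivity [image_volume()].
#' @export
sensitivity_image <- function(model, subset,
                              prc_mode = c("none", "simplified", "full"),
                              psf_enabled = FALSE, mask = NULL) {
  prc_mode <- match.arg(prc_mode)
  if (!length(subset)) stop("empty subset")
  geom <- model$geometry
  ones <- array(1, dim = c(geom$n_radial, length(subset), geom$image_dim[3]))
  w <- model_weights(model, subset)
  s <- back_project(ones * w, geom, angle_idx = subset)
  apply_h_adjoint(s, model, prc_mode, psf_enabled, mask = mask)
}

default_initial <- function(geom, fov_radius_mm = NULL) {
  if (is.null(fov_radius_mm))
    fov_radius_mm <- geom$n_radial * geom$radial_spacing / 2
  f <- image_volume(array(0, dim = geom$image_dim), geom$voxel_size)
  xc <- voxel_centers(f, 1); yc <- voxel_centers(f, 2)
  m <- outer(xc^2, yc^2, "+") <= fov_radius_mm^2
  vals <- f$values
  for (k in seq_len(geom$image_dim[3])) vals[, , k][m] <- 1
  vol_like(f, vals)
}

#' OSEM reconstruction with optional PSF and positron-range correction
#'
#' Ordered-subsets EM over the factorized system model `A = W * X * H`.
#' Per subset update: the current image is blurred with the resolution
#' factor H (spatially variant positron-range kernels if `prc_mode` is
#' not `"none"`, then the detector PSF if enabled), forward projected and
#' weighted; the measured-to-expected ratio is back projected with the
#' same weights; the adjoint of H is applied to the back projection only
#' for the PSF factor and, in `"full"` mode, the range factor; the image
#' is multiplied by the ratio of this correction term to the subset
#' sensitivity.  `"simplified"` mode deliberately mismatches forward and
#' backward projectors: the range blur enters the forward step only.
#'
#' @param proj measured `projection_data` (full sinogram).
#' @param model a [system_model()].
#' @param config a [recon_config()].
#' @return An object of class `recon_result`: `final_image`, optional
#'   `iterates` (one per full iteration), `config`, and `log` (per-update
#'   multiplier extrema and negativity-clip counts; clips are expected to
#'   be zero with a positive initialization and the epsilon guard).
#' @export
reconstruct <- function(proj, model, config = recon_config()) {
  geom <- model$geometry
  if (!identical(dim(proj$values)[c(1, 3)],
                 c(geom$n_radial, geom$image_dim[3])) ||
      dim(proj$values)[2] != geom$n_angles)
    stop("projection data does not match the model geometry")
  if (config$prc_mode != "none" && is.null(model$pr))
    stop("`prc_mode` requires positron-range kernels in the model")
  scheme <- partition_subsets(geom, config$n_subsets)
  m_all <- proj$values
  eps <- config$epsilon_scale * mean(m_all)

  f <- if (!is.null(config$initial_image)) config$initial_image
       else default_initial(geom, config$fov_radius_mm)
  check_fov(f, geom)
  support <- f$values > 0

  sens <- lapply(scheme$subsets, function(sub)
    sensitivity_image(model, sub, config$prc_mode, config$psf_enabled,
                      mask = support))
  iterates <- if (config$keep_iterates) vector("list", config$n_iterations)
  log <- data.frame(iteration = integer(), subset = integer(),
                    mult_min = numeric(), mult_max = numeric(),
                    clips = integer())

  for (it in seq_len(config$n_iterations)) {
    for (si in scheme$order) {
      sub <- scheme$subsets[[si]]
      w <- model_weights(model, sub)
      fb <- apply_h_forward(f, model, config$prc_mode, config$psf_enabled)
      y <- forward_project(fb, geom, angle_idx = sub)$values * w
      msub <- m_all[, sub, , drop = FALSE]
      ratio <- msub / (y + eps)
      bp <- back_project(ratio * w, geom, angle_idx = sub)
      bp <- apply_h_adjoint(bp, model, config$prc_mode, config$psf_enabled,
                            mask = support)
      sv <- sens[[si]]$values
      upd <- support & sv > 0
      mult <- bp$values[upd] / sv[upd]
      newv <- f$values
      newv[upd] <- f$values[upd] * mult
      clips <- sum(newv < 0)
      newv[newv < 0] <- 0
      f <- vol_like(f, newv)
      act <- f$values[upd] > 0
      log <- rbind(log, data.frame(iteration = it, subset = si,
                                   mult_min = min(mult[act]),
                                   mult_max = max(mult[act]),
                                   clips = clips))
    }
    if (config$keep_iterates) iterates[[it]] <- f
  }
  structure(list(final_image = f, iterates = iterates, config = config,
                 log = log),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %d iterations x %d subsets, prc %s, psf %s\n",
              x$config$n_iterations, x$config$n_subsets, x$config$prc_mode,
              if (x$config$psf_enabled) "on" else "off"))
  print(x$final_image)
  invisible(x)
}

#' The six named reconstruction variants
#'
#' Maps variant names to correction settings and default iteration
#' counts: OSEM, OSEM+PRC simplified, OSEM+PRC, PSF, PSF+PRC simplified
#' run 10 iterations; PSF+PRC, whose convergence is slowest, runs 20.
#' All use 12 subsets.
#'
#' @return data.frame with columns `variant`, `prc_mode`, `psf_enabled`,
#'   `n_iterations`.
#' @export
prc_variants <- function() {
  data.frame(
    variant = c("OSEM", "OSEM+PRC simplified", "OSEM+PRC",
                "PSF", "PSF+PRC simplified", "PSF+PRC"),
    prc_mode = c("none", "simplified", "full", "none", "simplified", "full"),
    psf_enabled = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    n_iterations = c(10L, 10L, 10L, 10L, 10L, 20L),
    stringsAsFactors = FALSE
  )
}

#' Run a list of reconstruction variants on the same data
#'
#' @param proj measured `projection_data`.
#' @param model a [system_model()] (must carry kernels for the PRC
#'   variants).
#' @param variants character vector of variant names from
#'   [prc_variants()].
#' @param n_subsets subsets per iteration.
#' @param n_iterations optional named vector overriding the per-variant
#'   default iteration counts.
#' @param fov_radius_mm passed to [recon_config()].
#' @return Named list of `recon_result`s with iterates kept.
#' @export
run_variant_suite <- function(proj, model,
                              variants = prc_variants()$variant,
                              n_subsets = 12L, n_iterations = NULL,
                              fov_radius_mm = NULL) {
  tab <- prc_variants()
  unknown <- setdiff(variants, tab$variant)
  if (length(unknown))
    stop("unknown variant name(s): ", paste(unknown, collapse = ", "))
  out <- vector("list", length(variants))
  names(out) <- variants
  for (v in variants) {
    row <- tab[tab$variant == v, ]
    iters <- if (!is.null(n_iterations) && v %in% names(n_iterations))
      n_iterations[[v]] else row$n_iterations
    cfg <- recon_config(n_iterations = iters, n_subsets = n_subsets,
                        prc_mode = row$prc_mode,
                        psf_enabled = row$psf_enabled,
                        keep_iterates = TRUE,
                        fov_radius_mm = fov_radius_mm)
    out[[v]] <- reconstruct(proj, model, cfg)
  }
  out
}
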