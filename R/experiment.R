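#' Experiment configuration
#'
#' Bundles every stage parameter of a phantom experiment: kernel bank,
#' phantom, acquisition, reconstruction variants and evaluation target.
#' Default total counts per phantom were calibrated once so that the
#' background noise of the uncorrected OSEM reconstruction reaches the
#' clinical ~10% working point (~33% for the small-tumor phantom) within
#' the variant's iteration range.
#'
#' @param phantom `"nema_iq"`, `"small_tumor"` or `"bone_lung"`.
#' @param grid image grid dimensions.
#' @param voxel_size voxel size in mm.
#' @param n_angles projection angles over `[0, pi)`.
#' @param n_subsets OSEM subsets.
#' @param total_counts expected total detected counts (default per
#'   phantom: 1.3e8 for nema_iq and bone_lung, 1.2e7 for small_tumor).
#' @param seed acquisition RNG seed.
#' @param psf_fwhm detector PSF FWHM in mm (used both in the simulation
#'   and in the PSF reconstruction variants).
#' @param kernel_events Monte-Carlo events per uniform kernel.
#' @param kernel_seed kernel-bank seed.
#' @param variants variant names from [prc_variants()].
#' @param n_iterations optional named per-variant iteration overrides.
#' @param target_noise_pct matched-noise target in percent.
#' @param phantom_args extra arguments for the phantom generator.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = c("nema_iq", "small_tumor",
                                          "bone_lung"),
                              grid = c(160L, 160L, 24L), voxel_size = 2,
                              n_angles = 96L, n_subsets = 12L,
                              total_counts = NULL, seed = 1L,
                              psf_fwhm = 4.4, kernel_events = 2e5,
                              kernel_seed = 1L,
                              variants = prc_variants()$variant,
                              n_iterations = NULL,
                              target_noise_pct = NULL,
                              phantom_args = list()) {
  phantom <- match.arg(phantom)
  if (is.null(total_counts))
    total_counts <- switch(phantom, nema_iq = 1.3e8, bone_lung = 1.3e8,
                           small_tumor = 1.2e7)
  if (is.null(target_noise_pct))
    target_noise_pct <- if (phantom == "small_tumor") 33 else 10
  structure(list(phantom = phantom, grid = as.integer(grid),
                 voxel_size = voxel_size, n_angles = as.integer(n_angles),
                 n_subsets = as.integer(n_subsets),
                 total_counts = total_counts, seed = as.integer(seed),
                 psf_fwhm = psf_fwhm, kernel_events = kernel_events,
                 kernel_seed = as.integer(kernel_seed),
                 variants = variants, n_iterations = n_iterations,
                 target_noise_pct = target_noise_pct,
                 phantom_args = phantom_args),
            class = "experiment_config")
}

#' Run a phantom experiment end to end
#'
#' Orchestrates kernels -> phantom -> acquisition simulation ->
#' reconstruction of every configured variant -> contrast/noise
#' evaluation.  Deterministic given the configured seeds.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory; when given, writes the
#'   phantom and final reconstructions (NIfTI), evaluation tables (CSV)
#'   and a JSON manifest (config, seeds, package version).
#' @param dry_run validate the configuration and return the execution
#'   plan without computing anything.
#' @param verbose print per-stage progress.
#' @return A list with `phantom`, `bank`, `model`, `proj`, `results`,
#'   `evaluation`, `matched` and `config` (invisibly the plan when
#'   `dry_run`).
#' @export
run_experiment <- function(config, out_dir = NULL, dry_run = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  plan <- list(stages = c("kernels", "phantom", "simulate",
                          paste0("reconstruct:", config$variants),
                          "evaluate"),
               config = config)
  if (dry_run) return(invisible(plan))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]

  say("stage kernels (%g events/material)", config$kernel_events)
  bank <- build_kernel_bank(voxel_size = config$voxel_size,
                            n_events = config$kernel_events,
                            seed = config$kernel_seed)

  say("stage phantom (%s)", config$phantom)
  gen <- switch(config$phantom, nema_iq = make_nema_iq,
                small_tumor = make_small_tumor, bone_lung = make_bone_lung)
  phantom <- do.call(gen, c(list(grid = config$grid,
                                 voxel_size = config$voxel_size),
                            config$phantom_args))

  mat_map <- segment_materials(phantom$hu)
  mu <- hu_to_mu(phantom$hu)
  geom <- scanner_geometry(config$grid, config$voxel_size,
                           n_angles = config$n_angles)
  att <- attenuation_factors(mu, geom)
  model <- system_model(geom, attenuation = att,
                        detector_fwhm = config$psf_fwhm,
                        pr = list(bank = bank, material_map = mat_map))

  say("stage simulate (%.3g counts)", config$total_counts)
  proj <- simulate_acquisition(phantom, model, config$total_counts,
                               seed = config$seed)

  # support constraint: emissions can only originate inside the body
  fov_r <- phantom_body_diameter(config) / 2
  results <- list()
  for (v in config$variants) {
    say("stage reconstruct: %s", v)
    results[[v]] <- run_variant_suite(proj, model, variants = v,
                                      n_subsets = config$n_subsets,
                                      n_iterations = config$n_iterations,
                                      fov_radius_mm = fov_r)[[1]]
  }

  say("stage evaluate")
  evaluation <- convergence_table(results, phantom$vois,
                                  phantom$activity_ratio)
  matched <- matched_noise_table(evaluation, config$target_noise_pct)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(phantom$activity, file.path(out_dir, "activity.nii.gz"))
    write_volume(phantom$hu, file.path(out_dir, "hu.nii.gz"))
    for (v in names(results))
      write_volume(results[[v]]$final_image,
                   file.path(out_dir, paste0("recon_", gsub("[ +]", "_", v),
                                             ".nii.gz")))
    write_evaluation(evaluation, out_dir, config$target_noise_pct)
    writeLines(jsonlite::toJSON(list(
      config = unclass(config),
      package_version = as.character(utils::packageVersion("prcrecon")),
      elapsed_s = round(proc.time()[3] - t0, 1)
    ), auto_unbox = TRUE, digits = NA, null = "null", force = TRUE),
    file.path(out_dir, "manifest.json"))
  }
  say("done in %.1f s", proc.time()[3] - t0)
  list(phantom = phantom, bank = bank, model = model, proj = proj,
       results = results, evaluation = evaluation, matched = matched,
       config = config)
}

phantom_body_diameter <- function(config) {
  if (!is.null(config$phantom_args$body_diameter))
    config$phantom_args$body_diameter else 286
}
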