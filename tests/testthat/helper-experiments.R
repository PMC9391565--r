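# full-scale simulation experiments shared by the acceptance checks;
# each runs once per test session and is reused across test blocks.
#
# Problem sizes: 160 x 160 x 24 voxels at 2 mm, 96 angles, 12 subsets,
# 2e7 total counts -- the package's scaled-down stand-in for the
# clinical acquisitions, small enough to run on one CPU in minutes.

nema_experiment <- function() {
  cached("nema_experiment", {
    cfg <- experiment_config("nema_iq", seed = 101L, kernel_seed = 1L)
    run_experiment(cfg)
  })
}

bone_lung_experiment <- function() {
  cached("bone_lung_experiment", {
    cfg <- experiment_config(
      "bone_lung", seed = 202L, kernel_seed = 1L,
      variants = c("OSEM", "OSEM+PRC"))
    run_experiment(cfg)
  })
}
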