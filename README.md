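# prcrecon

Positron range correction (PRC) inside iterative OSEM PET
reconstruction, with everything needed to study it end to end on
digital phantoms.

## The problem

PET assumes the positron annihilates where it was emitted.  For
high-energy emitters such as I-124 (beta-plus endpoints 1.5 and
2.1 MeV) the emission-to-annihilation displacement reaches ~10 mm in
water and several centimetres in lung.  This tissue-dependent blur
depresses the apparent uptake of small lesions far beyond the detector
resolution, and it cannot be removed by a stationary deconvolution
because it varies across the body.  The remedy studied here is to put
the range blur *into* the reconstruction's system model.

`prcrecon` is aimed at image-reconstruction researchers and medical
physicists who want a transparent, fully seeded sandbox for that idea:
every operator is exact, every experiment is reproducible from a
config and a seed, and the evaluation protocol mirrors standard
image-quality phantom practice.

## The model

The system matrix is factorized as

    A = W · X · H

where `X` holds exact voxel-intersection lengths along each line of
response (stacked-2D parallel-beam geometry), `W` the per-LOR
attenuation/normalization weights, and `H` an image-space resolution
factor: a parametric detector PSF and/or a spatially variant
positron-range blur.  The OSEM update over an angular subset `S` is

    f_j ← f_j / (Σ_{i∈S} (WXH)_ij) · (Hᵀ Xᵀ W)[ m / (W X H f) ]_j

Uniform per-material range kernels (lung 0.26, water 1.00, bone
1.92 g/cm³) are generated by a seeded Monte-Carlo sampler — beta-plus
spectrum with the positron Fermi factor, Katz–Penfold range scaled by
1/density, fixed tortuosity, isotropic emission — and composed per
voxel from a CT-derived material map (`ρ_k(h) = K_mat(k+h)(h)`,
renormalized).  Three correction modes are provided:

* **none** — `H` is at most the detector PSF;
* **full** — range blur in the forward projection, its exact adjoint
  in the back projection and the sensitivity image;
* **simplified** — range blur before the forward projection only
  (cheaper, but forward and backward projectors are mismatched).

Crossed with the PSF these give the six classic variants: `OSEM`,
`OSEM+PRC simplified`, `OSEM+PRC`, `PSF`, `PSF+PRC simplified`,
`PSF+PRC`.  Evaluation follows the NEMA-style protocol: per-sphere
contrast recovery `(MEAN_sphere / MEAN_background) / activity ratio`,
background noise `100·SD/MEAN` over pooled background VOIs,
matched-noise comparisons, and a radial-profile Gibbs overshoot
metric.

## Worked example

Small phantom, two reconstructions, compared at ~10% background noise
(runs in a couple of minutes):

```r
library(prcrecon)

# positron-range kernels for lung / soft tissue / bone (I-124)
bank <- build_kernel_bank(n_events = 1e5, seed = 1)
sapply(bank$kernels, kernel_fwhm)
#>     lung     soft     bone
#> 2.873360 2.561018 2.321614

# a compact image-quality phantom: hot spheres in a warm water cylinder
ph <- make_nema_iq(grid = c(96L, 96L, 16L), body_diameter = 170,
                   sphere_diameters = c(10, 13, 17, 22),
                   sphere_ring_diameter = 55, n_background_vois = 6L,
                   background_voi_diameter = 20, voi_clearance = 5)

# factorized system model A = W X H with PSF and ground-truth range blur
geom  <- scanner_geometry(dim(ph$activity$values), voxel_size = 2,
                          n_angles = 96L)
att   <- attenuation_factors(hu_to_mu(ph$hu), geom)
model <- system_model(geom, attenuation = att, detector_fwhm = 4.4,
                      pr = list(bank = bank,
                                material_map = segment_materials(ph$hu)))

# simulate a noisy acquisition and reconstruct two variants
proj <- simulate_acquisition(ph, model, total_counts = 4e7, seed = 7)
res  <- run_variant_suite(proj, model,
                          variants = c("OSEM", "OSEM+PRC"),
                          n_iterations = c("OSEM" = 4L, "OSEM+PRC" = 10L))

ev <- convergence_table(res, ph$vois, ph$activity_ratio)
mt <- matched_noise_table(ev, target_pct = 10)
mt[mt$sphere == "sphere_10mm", ]
#>   variant iteration noise_pct      sphere contrast_recovery
#>      OSEM         2 10.508877 sphere_10mm         0.4712659
#>  OSEM+PRC         8  9.556111 sphere_10mm         0.6219258
```

Reading the numbers: the kernel widths order by density (lung > water
> bone — positrons fly further in less dense media).  At comparable
background noise (~10%), modelling the positron range inside the
reconstruction lifts the 10 mm sphere's contrast recovery from 0.47
to 0.62; the full correction needs more iterations to get there
(8 vs 2) because its matched projector pair builds up noise much more
slowly.  Larger spheres gain less (0.75 → 0.82 for 22 mm), as partial
range blur matters most at lesion scale.

The same machinery scales to the built-in full experiments
(`run_experiment(experiment_config("nema_iq"))`, also `"small_tumor"`
and `"bone_lung"`), which add the six-variant comparison, convergence
tables and NIfTI/CSV/JSON outputs.  A thin command-line wrapper with
`kernels` / `phantom` / `simulate` / `reconstruct` / `evaluate` /
`run` subcommands ships in `inst/cli/prcrecon`.

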