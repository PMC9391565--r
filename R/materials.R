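#' Material specification for kernel generation and HU segmentation
#'
#' @param name material label.
#' @param mass_density mass density in g/cm^3.
#' @param hu_min,hu_max Hounsfield-unit interval `(hu_min, hu_max]` mapped
#'   to this material (use `-Inf` / `Inf` at the ends).
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, mass_density, hu_min, hu_max) {
  if (mass_density <= 0) stop("`mass_density` must be positive")
  if (hu_min >= hu_max) stop("`hu_min` must be below `hu_max`")
  structure(list(name = name, mass_density = mass_density,
                 hu_min = hu_min, hu_max = hu_max),
            class = "material_spec")
}

#' Default lung / soft-tissue / bone material set
#'
#' Mass densities 0.26 (lung-equivalent), 1.00 (water / soft tissue) and
#' 1.92 g/cm^3 (cortical bone).  HU thresholds: everything at or below
#' -150 HU (including air, which is treated as lung for positron-range
#' purposes) is lung; (-150, 150] is soft tissue; above 150 HU is bone.
#'
#' @return A named list of [material_spec()] objects partitioning the HU
#'   axis.
#' @export
default_materials <- function() {
  m <- list(
    lung = material_spec("lung", 0.26, -Inf, -150),
    soft = material_spec("soft", 1.00, -150, 150),
    bone = material_spec("bone", 1.92, 150, Inf)
  )
  validate_materials(m)
  m
}

# the HU intervals must partition the axis: sorted by hu_min, contiguous,
# covering (-Inf, Inf]
validate_materials <- function(materials) {
  if (!length(materials)) stop("need at least one material")
  ord <- order(vapply(materials, function(m) m$hu_min, numeric(1)))
  ms <- materials[ord]
  if (!is.infinite(ms[[1]]$hu_min) || ms[[1]]$hu_min > 0)
    if (ms[[1]]$hu_min != -Inf) stop("HU intervals must start at -Inf")
  for (i in seq_along(ms)[-1])
    if (ms[[i]]$hu_min != ms[[i - 1]]$hu_max)
      stop("HU intervals must partition the axis (gap or overlap found)")
  if (ms[[length(ms)]]$hu_max != Inf)
    stop("HU intervals must end at Inf")
  invisible(materials)
}
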