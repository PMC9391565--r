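voi_voxels <- function(image, center, diameter, label = "VOI") {
  xc <- voxel_centers(image, 1)
  yc <- voxel_centers(image, 2)
  zc <- voxel_centers(image, 3)
  r2 <- (diameter / 2)^2
  ix <- which((xc - center[1])^2 <= r2)
  iy <- which((yc - center[2])^2 <= r2)
  iz <- which((zc - center[3])^2 <= r2)
  if (!length(ix) || !length(iy) || !length(iz))
    stop(sprintf("VOI '%s' contains no voxel centres", label))
  d2 <- outer(outer((xc[ix] - center[1])^2, (yc[iy] - center[2])^2, "+"),
              (zc[iz] - center[3])^2, "+")
  vals <- image$values[ix, iy, iz][d2 <= r2]
  if (!length(vals))
    stop(sprintf("VOI '%s' contains no voxel centres", label))
  vals
}

pooled_background <- function(image, background_vois) {
  unlist(lapply(seq_len(nrow(background_vois)), function(j)
    voi_voxels(image,
               unlist(background_vois[j, c("x", "y", "z")]),
               background_vois$diameter[j],
               background_vois$label[j])))
}

#' Contrast recovery per sphere
#'
#' For each sphere VOI, `(sphere mean / background mean) / activity
#' ratio`, where the background mean is taken over the voxels of all
#' background VOIs pooled.  VOI membership is by the voxel-centre-inside-
#' sphere rule.  Perfect recovery gives 1; zero contrast gives
#' `1 / activity_ratio`.
#'
#' @param image reconstructed [image_volume()].
#' @param vois a [voi_set()].
#' @param activity_ratio true hot/background concentration ratio.
#' @return Named numeric vector, one value per sphere VOI.
#' @export
contrast_recovery <- function(image, vois, activity_ratio) {
  if (activity_ratio <= 0) stop("`activity_ratio` must be positive")
  bg <- pooled_background(image, vois$background_vois)
  bg_mean <- mean(bg)
  sv <- vois$sphere_vois
  out <- vapply(seq_len(nrow(sv)), function(i) {
    s <- voi_voxels(image, unlist(sv[i, c("x", "y", "z")]),
                    sv$diameter[i], sv$label[i])
    (mean(s) / bg_mean) / activity_ratio
  }, numeric(1))
  names(out) <- sv$label
  out
}

#' Percent background noise
#'
#' `100 * SD / mean` over the pooled voxels of all background VOIs (the
#' coefficient of variation in percent).  The population (divide-by-n)
#' standard deviation is used for determinism; at thousands of pooled
#' voxels the n vs n-1 difference is negligible.
#'
#' @param image reconstructed [image_volume()].
#' @param background_vois background VOI table (or a [voi_set()]).
#' @return Noise in percent.
#' @export
image_noise <- function(image, background_vois) {
  if (inherits(background_vois, "voi_set"))
    background_vois <- background_vois$background_vois
  if (!nrow(background_vois)) stop("need at least one background VOI")
  bg <- pooled_background(image, background_vois)
  m <- mean(bg)
  if (m == 0) stop("zero background mean: noise (CV) undefined")
  sd_pop <- sqrt(mean((bg - m)^2))
  100 * sd_pop / m
}

#' Per-iteration contrast recovery and noise for a variant suite
#'
#' @param results named list of `recon_result`s with iterates kept
#'   (from [run_variant_suite()]).
#' @param vois a [voi_set()].
#' @param activity_ratio true hot/background concentration ratio.
#' @return An object of class `evaluation_result` holding
#'   `per_iteration`: a tidy data.frame with columns `variant`,
#'   `iteration`, `sphere`, `contrast_recovery`, `noise_pct`.
#' @export
convergence_table <- function(results, vois, activity_ratio) {
  rows <- list()
  for (v in names(results)) {
    res <- results[[v]]
    if (is.null(res$iterates) || !length(res$iterates) ||
        is.null(res$iterates[[1]]))
      stop(sprintf("variant '%s' has no kept iterates", v))
    for (it in seq_along(res$iterates)) {
      img <- res$iterates[[it]]
      cr <- contrast_recovery(img, vois, activity_ratio)
      noise <- image_noise(img, vois)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = v, iteration = it,
                   sphere = names(cr), contrast_recovery = unname(cr),
                   noise_pct = noise, stringsAsFactors = FALSE)
    }
  }
  structure(list(per_iteration = do.call(rbind, rows)),
            class = "evaluation_result")
}

#' Select the iteration matching a target background noise
#'
#' Per variant, the iteration whose noise is closest to the target (ties
#' broken toward the lower iteration).  Flagged unreachable when the
#' final-iteration noise is still more than 5 percentage points below
#' the target.
#'
#' @param per_iteration the `per_iteration` table of an
#'   `evaluation_result` (or the object itself).
#' @param target_pct target background noise in percent.
#' @return data.frame with one row per variant: `variant`, `iteration`,
#'   `noise_pct`, `unreachable`.
#' @export
select_iteration_at_noise <- function(per_iteration, target_pct = 10) {
  if (inherits(per_iteration, "evaluation_result"))
    per_iteration <- per_iteration$per_iteration
  if (!nrow(per_iteration)) stop("empty per-iteration table")
  out <- lapply(split(per_iteration, per_iteration$variant), function(tab) {
    noise <- tapply(tab$noise_pct, tab$iteration, function(x) x[1])
    its <- as.integer(names(noise))
    o <- order(its)
    its <- its[o]; noise <- as.numeric(noise)[o]
    best <- its[which.min(abs(noise - target_pct))]
    data.frame(variant = tab$variant[1], iteration = best,
               noise_pct = noise[match(best, its)],
               unreachable = max(noise) < target_pct - 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Contrast recovery at matched noise
#'
#' Convenience: combine [select_iteration_at_noise()] with the
#' per-iteration table to report each variant's contrast recovery at its
#' matched-noise iteration.
#'
#' @inheritParams select_iteration_at_noise
#' @return data.frame with columns `variant`, `iteration`, `noise_pct`,
#'   `sphere`, `contrast_recovery`.
#' @export
matched_noise_table <- function(per_iteration, target_pct = 10) {
  if (inherits(per_iteration, "evaluation_result"))
    per_iteration <- per_iteration$per_iteration
  sel <- select_iteration_at_noise(per_iteration, target_pct)
  out <- merge(sel[, c("variant", "iteration", "noise_pct")],
               per_iteration[, c("variant", "iteration", "sphere",
                                 "contrast_recovery")],
               by = c("variant", "iteration"))
  out[order(out$variant, out$sphere), ]
}

#' Edge overshoot (Gibbs) of a reconstructed sphere
#'
#' Samples a radial profile through the sphere centre in its transaxial
#' plane — bilinearly interpolated and averaged over profile angles —
#' and reports `100 * (max(profile) - true_activity) / true_activity`,
#' clipped at 0.  Resolution-modelling reconstructions overshoot at
#' sharp activity borders (Gibbs ringing); unregularized OSEM at
#' moderate iteration numbers does not.  The angular average keeps the
#' coherent Gibbs rim (which surrounds the whole sphere) while
#' suppressing the voxel noise that would dominate the maximum of any
#' single line profile.
#'
#' @param image reconstructed [image_volume()].
#' @param center sphere centre (mm, length 3).
#' @param diameter sphere diameter (mm).
#' @param true_activity true sphere concentration.
#' @param background_activity true background concentration (must be
#'   below `true_activity` for the overshoot to be meaningful).
#' @param margin_mm profile margin beyond the sphere radius.
#' @param n_angles number of profile directions averaged.
#' @return Overshoot in percent (>= 0).
#' @export
edge_overshoot <- function(image, center, diameter, true_activity,
                           background_activity, margin_mm = 2,
                           n_angles = 72L) {
  if (true_activity <= background_activity)
    stop("degenerate profile: sphere must be hotter than background")
  xc <- voxel_centers(image, 1)
  yc <- voxel_centers(image, 2)
  zc <- voxel_centers(image, 3)
  iz <- which.min(abs(zc - center[3]))
  plane <- image$values[, , iz]
  # search the outer half of the sphere plus a margin: the Gibbs rim
  # sits at the edge, and both the central EM transient of hot objects
  # and the degenerate (few-voxel) angular average near r = 0 would
  # otherwise masquerade as overshoot
  radii <- seq(diameter / 4, diameter / 2 + margin_mm,
               by = min(image$voxel_size[1:2]) / 4)
  ang <- (seq_len(n_angles) - 1L) * 2 * pi / n_angles
  interp <- function(px, py) {
    # bilinear interpolation on the plane; outside the grid -> NA
    fx <- (px - xc[1]) / image$voxel_size[1] + 1
    fy <- (py - yc[1]) / image$voxel_size[2] + 1
    i0 <- floor(fx); j0 <- floor(fy)
    if (any(i0 < 1 | i0 + 1 > length(xc) | j0 < 1 | j0 + 1 > length(yc)))
      stop("degenerate profile: sphere too close to the volume edge")
    wx <- fx - i0; wy <- fy - j0
    plane[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
      plane[cbind(i0 + 1, j0)] * wx * (1 - wy) +
      plane[cbind(i0, j0 + 1)] * (1 - wx) * wy +
      plane[cbind(i0 + 1, j0 + 1)] * wx * wy
  }
  prof <- vapply(radii, function(r)
    mean(interp(center[1] + r * cos(ang), center[2] + r * sin(ang))),
    numeric(1))
  max(0, 100 * (max(prof) - true_activity) / true_activity)
}

#' Export an evaluation to CSV
#'
#' Writes the per-iteration table and, if a target noise is given, the
#' matched-noise summary.
#'
#' @param eval_result an `evaluation_result`.
#' @param dir output directory.
#' @param target_pct optional matched-noise target in percent.
#' @return The directory, invisibly.
#' @export
write_evaluation <- function(eval_result, dir, target_pct = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(eval_result$per_iteration,
            file.path(dir, "per_iteration.csv"), row.names = FALSE)
  if (!is.null(target_pct))
    write.csv(matched_noise_table(eval_result, target_pct),
              file.path(dir, "matched_noise.csv"), row.names = FALSE)
  invisible(dir)
}
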