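#' Positron emission spectrum of a beta-plus emitter
#'
#' A spectrum is a set of beta-plus decay branches, each with an endpoint
#' (maximum) kinetic energy and a branching fraction.  Branching fractions
#' may sum to less than one (the remainder being non-positron decay
#' channels); displacement sampling renormalizes over the positron
#' branches only.
#'
#' @param endpoint_energy numeric vector of branch endpoint energies (MeV).
#' @param branching_fraction numeric vector of branch intensities per decay.
#' @param isotope isotope label.
#' @return An object of class `positron_spectrum`.
#' @export
positron_spectrum <- function(endpoint_energy, branching_fraction,
                              isotope = "custom") {
  if (length(endpoint_energy) != length(branching_fraction) ||
      length(endpoint_energy) < 1L)
    stop("need >= 1 branch with matching endpoint/fraction lengths")
  if (any(endpoint_energy < 0) || any(branching_fraction <= 0))
    stop("endpoint energies must be >= 0 and fractions > 0")
  if (sum(branching_fraction) > 1 + 1e-9)
    stop("branching fractions must sum to <= 1")
  structure(list(branches = data.frame(endpoint_energy = endpoint_energy,
                                       branching_fraction = branching_fraction),
                 isotope = isotope),
            class = "positron_spectrum")
}

#' I-124 positron spectrum
#'
#' The two main beta-plus branches of I-124: endpoint energies 1.535 and
#' 2.138 MeV with intensities 11.8% and 10.8% per decay (total positron
#' branching about 23%), the remainder of the decays being electron
#' capture.  The high endpoint energies give I-124 its unusually large
#' positron range (about 10 mm maximum in water), which is what makes
#' range correction worthwhile for this isotope.
#'
#' @return A [positron_spectrum()].
#' @export
i124_positron_spectrum <- function() {
  positron_spectrum(endpoint_energy = c(1.535, 2.138),
                    branching_fraction = c(0.118, 0.108),
                    isotope = "I124")
}

#' Allowed beta-plus spectrum shape
#'
#' Unnormalized allowed-transition spectrum
#' `N(E) = F(Z, E) * p * W * (Q - E)^2` with total energy `W = E + m_e`,
#' momentum `p = sqrt(W^2 - m_e^2)` (all in MeV, `m_e = 0.511`) and the
#' non-relativistic Coulomb (Fermi) factor for positron emission,
#' `F = x / (1 - exp(-x))` with `x = -2 pi Z alpha / beta`.  The Coulomb
#' repulsion of the daughter nucleus suppresses slow positrons
#' exponentially; without it the low-energy (short-range) tail of the
#' annihilation kernel is strongly overweighted.
#'
#' @param energy positron kinetic energy in MeV.
#' @param endpoint branch endpoint energy in MeV.
#' @param z_daughter atomic number of the daughter nucleus (default 52,
#'   Te for I-124 decay).
#' @return Unnormalized density values (0 outside `(0, endpoint)`).
#' @export
beta_spectrum_pdf <- function(energy, endpoint, z_daughter = 52) {
  me <- 0.511
  w <- energy + me
  p <- sqrt(pmax(w^2 - me^2, 0))
  beta <- ifelse(w > 0, p / w, 0)
  x <- -2 * pi * z_daughter / 137.036 * ifelse(beta > 0, 1 / beta, Inf)
  fermi <- ifelse(beta > 0, x / (1 - exp(-x)), 0)
  out <- fermi * p * w * (endpoint - energy)^2
  out[energy < 0 | energy > endpoint] <- 0
  out
}

#' Empirical positron range from kinetic energy
#'
#' Extrapolated range from the Katz-Penfold relation
#' `R [g/cm^2] = 0.412 * E^(1.265 - 0.0954 ln E)` (E in MeV, valid to
#' 2.5 MeV), converted to mm by dividing by the mass density.  Range is
#' taken inversely proportional to mass density; electron-density
#' differences between tissues are ignored.
#'
#' @param energy positron kinetic energy in MeV.
#' @param density mass density in g/cm^3.
#' @return Range in mm (0 for non-positive energies).
#' @export
positron_range_mm <- function(energy, density) {
  if (any(density <= 0)) stop("`density` must be positive")
  r <- numeric(length(energy))
  ok <- energy > 0
  e <- energy[ok]
  r[ok] <- 0.412 * e^(1.265 - 0.0954 * log(e))
  r / density * 10
}

# Inverse-CDF sample of kinetic energies from one branch (allowed shape),
# using a fine tabulated CDF.  `u` are uniform(0,1) draws.
sample_branch_energy <- function(u, endpoint, n_grid = 4096L) {
  if (endpoint <= 0) return(rep(0, length(u)))
  e <- seq(0, endpoint, length.out = n_grid)
  d <- beta_spectrum_pdf(e, endpoint)
  cdf <- cumsum((d[-1] + d[-n_grid]) / 2 * diff(e))
  cdf <- c(0, cdf / cdf[n_grid - 1L])
  approx(cdf, e, xout = u, ties = "ordered")$y
}

#' Sample positron annihilation displacements
#'
#' Draws 3D emission-to-annihilation displacement vectors for a positron
#' spectrum in a uniform material: (a) a beta-plus branch is sampled by
#' branching fraction, (b) the initial kinetic energy is drawn from the
#' allowed beta spectrum shape of that branch, (c) the energy is converted
#' to a path length by the Katz-Penfold range relation scaled by
#' 1/density, (d) a fixed tortuosity factor converts path length to an
#' effective radial displacement, emitted in an isotropically drawn
#' direction.  The random stream does not depend on `density`, so matched
#' seeds give displacement sets related by the exact density ratio.
#'
#' @param spectrum a [positron_spectrum()].
#' @param density material mass density in g/cm^3.
#' @param n number of annihilation events to draw.
#' @param tortuosity fixed factor (<= 1) converting path length to net
#'   radial displacement; accounts for trajectory curvature.
#' @return `n x 3` matrix of displacements in mm.
#' @export
sample_annihilation_displacement <- function(spectrum, density, n = 1L,
                                             tortuosity = 0.9) {
  if (!inherits(spectrum, "positron_spectrum"))
    stop("`spectrum` must be a positron_spectrum")
  if (length(density) != 1L || !is.finite(density) || density <= 0)
    stop("invalid material: `density` must be a single positive number")
  if (tortuosity <= 0 || tortuosity > 1)
    stop("`tortuosity` must be in (0, 1]")
  br <- spectrum$branches
  prob <- br$branching_fraction / sum(br$branching_fraction)
  bidx <- sample.int(nrow(br), n, replace = TRUE, prob = prob)
  u <- runif(n)
  energy <- numeric(n)
  for (b in seq_len(nrow(br))) {
    sel <- bidx == b
    if (any(sel))
      energy[sel] <- sample_branch_energy(u[sel], br$endpoint_energy[b])
  }
  radius <- tortuosity * positron_range_mm(energy, density)
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(x = radius * rho * cos(phi),
        y = radius * rho * sin(phi),
        z = radius * z)
}
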