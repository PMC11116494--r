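#' Lennard-Jones crowder (BSA) model
#'
#' Crowders are single Lennard-Jones spheres parameterised by the pair
#' distance of minimum energy (Rmin) and well depth. The DNA-crowder cross
#' interaction uses `epsilon_cd_per_nt * nt_per_bead` for the well depth and,
#' by default, Lorentz-style mixing of the per-species Rmin values for the
#' cross Rmin.
#'
#' @param rmin Crowder-crowder Rmin (nm, default 3.9).
#' @param epsilon Crowder-crowder well depth (kcal/mol, default 0.1).
#' @param damping Damping rate (1/ns, default 215); the diffusivity is
#'   `kT / (mass * damping)`.
#' @param concentration Molar concentration (mol/L, default 4.5e-3).
#' @param epsilon_cd_per_nt DNA-crowder well depth per nucleotide
#'   represented by a DNA bead (kcal/mol, default 0.05).
#' @param mass Crowder mass (Da; default 66500, BSA).
#' @param cross_rmin Either `"lorentz"` (cross Rmin = (Rmin_dd + Rmin_cc)/2)
#'   or a number giving the cross Rmin directly (nm).
#' @param temperature Kelvin.
#' @return An object of class `nj_crowder_model`.
#' @export
crowder_model <- function(rmin = 3.9, epsilon = 0.1, damping = 215,
                          concentration = 4.5e-3, epsilon_cd_per_nt = 0.05,
                          mass = 66500, cross_rmin = "lorentz",
                          temperature = 291) {
  if (any(c(rmin, epsilon, damping, mass) <= 0) || concentration < 0)
    stop("crowder parameters must be positive (concentration >= 0)")
  structure(list(
    rmin_cc = rmin, epsilon_cc = epsilon, damping = damping,
    concentration = concentration, epsilon_cd_per_nt = epsilon_cd_per_nt,
    mass = mass, cross_rmin = cross_rmin, temperature = temperature,
    D = damping_to_D(damping, mass, temperature)
  ), class = "nj_crowder_model")
}

#' @exportS3Method base::print
print.nj_crowder_model <- function(x, ...) {
  cat(sprintf(
    "Crowder model: Rmin %g nm, eps %g kcal/mol, %g mM, D %.3g nm^2/ns\n",
    x$rmin_cc, x$epsilon_cc, x$concentration * 1e3, x$D))
  invisible(x)
}

# resolved DNA-crowder pair parameters for a given DNA model
crowder_cross_pars <- function(crowders, dna) {
  rmin_cd <- if (identical(crowders$cross_rmin, "lorentz")) {
    (dna$bead_rmin + crowders$rmin_cc) / 2
  } else {
    as.numeric(crowders$cross_rmin)
  }
  list(rmin_cd = rmin_cd,
       eps_cd = crowders$epsilon_cd_per_nt * dna$nt_per_bead)
}

#' Number of crowders at a molar concentration in a volume
#'
#' @param volume_nm3 Volume in nm^3.
#' @param concentration Molar concentration (mol/L).
#' @return Integer count, `round(c * N_A * V)`.
#' @export
crowder_count <- function(volume_nm3, concentration) {
  if (concentration < 0) stop("concentration must be >= 0")
  round(concentration * avogadro() * volume_nm3 * 1e-24)
}

#' Random placement of crowders in the fluid
#'
#' Places `round(c * N_A * V)` crowders uniformly in the fluid, keeping
#' `margin` away from walls. By default they occupy the bath only (z < 0);
#' `region = "all"` distributes them through the whole system, bath and
#' pipette interior alike. Reproducible for a fixed seed.
#'
#' @param geom An `nj_geometry`.
#' @param concentration Molar concentration (mol/L).
#' @param seed Integer seed (optional; uses the current RNG state if NULL).
#' @param margin Clearance from walls (nm).
#' @param region `"bath"` (z < 0 only, the default) or `"all"` (bath plus
#'   pipette interior).
#' @return n x 3 matrix of crowder positions (nm).
#' @export
place_crowders <- function(geom, concentration, seed = NULL, margin = 1.5,
                           region = c("bath", "all")) {
  region <- match.arg(region)
  if (concentration < 0) stop("concentration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  m <- geom$wall_margin + margin
  half <- geom$bath_box[1] / 2 - m
  depth <- geom$bath_box[3] - m
  vol_bath <- (2 * half)^2 * (depth - margin)
  a <- geom$aperture_diameter / 2
  # cone interior volume with the margin peeled off the wall
  rz <- function(z) pmax(cone_radius(geom, z) - margin, 0)
  vol_cone <- if (region == "all") {
    stats::integrate(function(z) pi * rz(z)^2, 0,
                     geom$pipette_length - m)$value
  } else 0
  n <- crowder_count(vol_bath + vol_cone, concentration)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  n_cone <- round(n * vol_cone / (vol_bath + vol_cone))
  bath <- cbind(stats::runif(n - n_cone, -half, half),
                stats::runif(n - n_cone, -half, half),
                stats::runif(n - n_cone, -depth, -margin))
  if (n_cone == 0) return(bath)
  # rejection-sample uniformly inside the margin-shrunk cone
  zmax <- geom$pipette_length - m
  rmax <- rz(zmax)
  cone <- matrix(NA_real_, 0, 3)
  while (nrow(cone) < n_cone) {
    k <- 4 * (n_cone - nrow(cone)) + 16
    cand <- cbind(stats::runif(k, -rmax, rmax), stats::runif(k, -rmax, rmax),
                  stats::runif(k, 0, zmax))
    ok <- cand[, 1]^2 + cand[, 2]^2 < rz(cand[, 3])^2
    cone <- rbind(cone, cand[ok, , drop = FALSE])
  }
  rbind(bath, cone[seq_len(n_cone), , drop = FALSE])
}

#' Lennard-Jones potential in Rmin/epsilon form
#'
#' `U(r) = eps * ((Rmin/r)^12 - 2 (Rmin/r)^6)`: minimum of depth `-eps` at
#' Rmin, vanishing at large r.
#'
#' @param r Separation (nm), > 0.
#' @param rmin Distance of minimum energy (nm).
#' @param epsilon Well depth (kcal/mol).
#' @return Potential energy (kcal/mol).
#' @export
lj_potential <- function(r, rmin, epsilon) {
  if (any(r <= 0)) stop("r must be > 0")
  s6 <- (rmin / r)^6
  epsilon * (s6^2 - 2 * s6)
}

#' Signed radial Lennard-Jones force
#'
#' `F(r) = -dU/dr = 12 eps / r ((Rmin/r)^12 - (Rmin/r)^6)`; positive =
#' repulsive. Below `cap_r = 0.6 Rmin` the magnitude is capped at its value
#' at `cap_r` so overlapping initial placements cannot produce unbounded
#' forces.
#'
#' @inheritParams lj_potential
#' @param cap Logical; apply the small-separation force cap (default TRUE).
#' @return Force (kcal/mol/nm).
#' @export
lj_force <- function(r, rmin, epsilon, cap = TRUE) {
  if (any(r <= 0)) stop("r must be > 0")
  re <- if (cap) pmax(r, 0.6 * rmin) else r
  s6 <- (rmin / re)^6
  12 * epsilon / re * (s6^2 - s6)
}
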