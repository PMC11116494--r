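#' Coarse-grained bead-spring model of linear dsDNA
#'
#' One bead represents `nt_per_bead` nucleotides (`nt_per_bead / 2` base
#' pairs). Bonded terms are harmonic bonds at the contour rise plus a
#' discrete worm-like-chain bending term `k_bend * (1 - cos phi)`, with
#' `k_bend` solved so the chain's persistence length equals
#' `persistence_length` exactly for the discrete chain:
#' `<cos phi> = coth(a) - 1/a = exp(-b / Lp)` with `a = k_bend / kT`.
#'
#' @param n_bp Number of base pairs (>= 10).
#' @param nt_per_bead Nucleotides per bead (even, >= 2). Default 10 (5 bp).
#' @param rise_per_bp Helical rise (nm/bp, default 0.34).
#' @param persistence_length Target persistence length (nm, default 50).
#' @param bond_stiffness Bond spring constant (kcal/mol/nm^2).
#' @param charge_per_nt Effective charge per nucleotide (e; default -0.25,
#'   Manning-condensation-scaled).
#' @param rmin Lennard-Jones Rmin of a DNA bead (nm, default 1.1).
#' @param epsilon_self Well depth of the soft self-exclusion term (kcal/mol);
#'   applied purely repulsively (truncated at Rmin).
#' @param temperature Kelvin.
#' @param viscosity Solvent viscosity (Pa s) for the Stokes-Einstein bead
#'   diffusivity.
#' @return An object of class `nj_dna_model`.
#' @export
build_dna <- function(n_bp, nt_per_bead = 10, rise_per_bp = 0.34,
                      persistence_length = 50, bond_stiffness = 50,
                      charge_per_nt = -0.25, rmin = 1.1, epsilon_self = 0.05,
                      temperature = 291, viscosity = 1.06e-3) {
  if (n_bp < 10) stop("n_bp must be >= 10")
  if (nt_per_bead < 2 || nt_per_bead %% 2 != 0)
    stop("nt_per_bead must be even and >= 2")
  if (nt_per_bead > 2 * n_bp) stop("nt_per_bead exceeds the molecule size")
  n_beads <- ceiling(2 * n_bp / nt_per_bead)
  bp_per_bead <- nt_per_bead / 2
  b <- rise_per_bp * bp_per_bead
  kT <- kT_kcal(temperature)
  # discrete WLC stiffness: solve coth(a) - 1/a = exp(-b/Lp)
  target <- exp(-b / persistence_length)
  f <- function(a) 1 / tanh(a) - 1 / a - target
  alpha <- stats::uniroot(f, c(1e-3, 1e5), tol = 1e-12)$root
  D <- stokes_einstein_D(rmin, temperature, viscosity)
  mass <- nt_per_bead * 325 # ~average nucleotide mass, Da
  structure(list(
    n_bp = n_bp, nt_per_bead = nt_per_bead, n_beads = n_beads,
    bp_per_bead = bp_per_bead,
    bond_rest_length = b, bond_stiffness = bond_stiffness,
    bending_stiffness = alpha * kT, alpha = alpha,
    persistence_length = persistence_length,
    contour_length = n_beads * b,
    charge_per_bead = charge_per_nt * nt_per_bead,
    bead_rmin = rmin, epsilon_self = epsilon_self,
    bead_D = D, bead_damping = kT * kcalmol_to_da_nm2_ns2() / (mass * D),
    mass = mass, temperature = temperature
  ), class = "nj_dna_model")
}

#' @exportS3Method base::print
print.nj_dna_model <- function(x, ...) {
  cat(sprintf("dsDNA model: %d bp, %d beads (%g bp/bead), contour %.1f nm\n",
              x$n_bp, x$n_beads, x$bp_per_bead, x$contour_length))
  cat(sprintf("  Lp %g nm (k_bend %.3g kcal/mol), charge %.2f e/bead, D %.3g nm^2/ns\n",
              x$persistence_length, x$bending_stiffness, x$charge_per_bead,
              x$bead_D))
  invisible(x)
}

#' Bonded and self-exclusion forces of the chain
#'
#' Analytic forces (and energy) from bonds, bending angles, and the soft
#' repulsive self-exclusion term. Net force and net torque vanish by
#' construction (translation/rotation invariance).
#'
#' @param state An `nj_polymer_state` or a bare n x 3 position matrix.
#' @param model The `nj_dna_model` (taken from the state if missing).
#' @return n x 3 matrix of forces (kcal/mol/nm), with the total potential
#'   energy (kcal/mol) in attribute `"energy"`.
#' @export
internal_forces <- function(state, model = NULL) {
  pos <- polymer_positions(state)
  if (is.null(model)) model <- attr(state, "model")
  if (any(!is.finite(pos))) stop("non-finite bead positions")
  res <- dna_internal_cpp(pos, model$bond_stiffness, model$bond_rest_length,
                          model$bending_stiffness, model$bead_rmin,
                          model$epsilon_self)
  structure(res$forces, energy = res$energy)
}

#' Total bonded + self-exclusion energy of the chain (kcal/mol)
#'
#' @inheritParams internal_forces
#' @export
internal_energy <- function(state, model = NULL) {
  attr(internal_forces(state, model), "energy")
}

polymer_positions <- function(state) {
  if (is.matrix(state)) {
    storage.mode(state) <- "double"
    return(state)
  }
  if (inherits(state, "nj_polymer_state")) return(state$positions)
  stop("expected a position matrix or nj_polymer_state")
}

#' Polymer state
#'
#' Bead positions bound to their model, with a chain-integrity check:
#' consecutive bead distances must lie within [0.2, 3] x the rest length.
#'
#' @param positions n x 3 matrix (nm).
#' @param model An `nj_dna_model`.
#' @export
polymer_state <- function(positions, model) {
  storage.mode(positions) <- "double"
  if (nrow(positions) != model$n_beads)
    stop("positions do not match model bead count")
  d <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                       positions[-nrow(positions), , drop = FALSE])^2))
  if (any(d < 0.2 * model$bond_rest_length | d > 3 * model$bond_rest_length))
    stop("chain integrity violated: bond length outside [0.2, 3] x rest length")
  structure(list(positions = positions, model = model),
            class = "nj_polymer_state")
}

#' Radius of gyration
#'
#' Root-mean-square distance of points from their centroid.
#'
#' @param positions m x 3 matrix (nm), m >= 1.
#' @return Length (nm).
#' @export
radius_of_gyration <- function(positions) {
  positions <- to_pos_matrix(positions)
  if (nrow(positions) == 0) stop("radius of gyration of an empty set")
  ctr <- colMeans(positions)
  sqrt(mean(rowSums(sweep(positions, 2, ctr)^2)))
}

#' Closed-form worm-like-chain radius of gyration (Benoit-Doty)
#'
#' Ideal-chain reference for a contour length `L` and persistence length
#' `Lp`.
#'
#' @param L Contour length (nm).
#' @param Lp Persistence length (nm).
#' @return Rg (nm).
#' @export
wlc_rg_theory <- function(L, Lp) {
  sqrt(Lp * L / 3 - Lp^2 + 2 * Lp^3 / L -
         2 * Lp^4 / L^2 * (1 - exp(-L / Lp)))
}

#' Direct equilibrium sampling of the discrete worm-like chain
#'
#' Draws independent equilibrium configurations of the chain's bending
#' ensemble (bond length fixed at the rest length, no excluded volume) by
#' inverse-CDF sampling of the deflection-angle Boltzmann weight. Serves as
#' an equilibrium reference route that bypasses the dynamics engine.
#'
#' @param model An `nj_dna_model`.
#' @param n_chains Number of chains to draw.
#' @return Numeric vector of per-chain radii of gyration (nm).
#' @export
sample_wlc_rg <- function(model, n_chains = 500) {
  sample_wlc_rg_cpp(model$n_beads, model$bond_rest_length, model$alpha,
                    n_chains)
}

#' Initial DNA placement inside the pipette ("stuffing")
#'
#' Grows the chain upward from the aperture along the pipette axis with
#' small random lateral displacements, keeping every bead inside the cone
#' with a safety margin. The leading (lowest) bead is placed `start_depth`
#' above the aperture plane.
#'
#' @param model An `nj_dna_model`.
#' @param geom An `nj_geometry`.
#' @param start_depth Height (nm) of the chain end nearest the aperture.
#' @param margin Lateral clearance from the cone wall (nm).
#' @return An `nj_polymer_state`.
#' @export
init_dna_in_pipette <- function(model, geom, start_depth, margin = 2) {
  n <- model$n_beads
  b <- model$bond_rest_length
  dz <- 0.92 * b
  lat <- sqrt(b^2 - dz^2)
  pos <- matrix(0, n, 3)
  pos[1, ] <- c(0, 0, start_depth)
  if (start_depth + (n - 1) * dz > geom$pipette_length - geom$wall_margin - 2)
    stop("chain does not fit in the pipette above start_depth; ",
         "increase pipette_length")
  for (i in seq_len(n - 1)) {
    ang <- stats::runif(1, 0, 2 * pi)
    cand <- pos[i, ] + c(lat * cos(ang), lat * sin(ang), dz)
    rmax <- max(cone_radius(geom, cand[3]) - margin, 0.5)
    rad <- sqrt(cand[1]^2 + cand[2]^2)
    if (rad > rmax) cand[1:2] <- cand[1:2] * rmax / rad
    pos[i + 1, ] <- cand
  }
  polymer_state(pos, model)
}
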