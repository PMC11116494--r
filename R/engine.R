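#' Simulation parameters
#'
#' Bundles the integrator and protocol settings. Two presets are provided:
#' `"desk_scale"` (the default: a reduced system that runs in minutes on one
#' CPU) and `"paper_scale"` (the full published protocol: 40 fs timestep,
#' 50-100 us equilibration, 24 replicas, start depths 100/185/270 nm; meant
#' for cluster use).
#'
#' @param timestep Integration timestep (ns).
#' @param temperature Kelvin (default 291).
#' @param bias Applied bias magnitude (mV, default 600, ejecting polarity).
#' @param equilibration_time Field-free equilibration (ns).
#' @param max_time Production cap (ns); runs that do not fully eject by then
#'   are flagged incomplete.
#' @param post_eject_time Extra simulation time after full ejection (ns), so
#'   post-translocation relaxation (radius of gyration, centre-of-mass
#'   spread) is observable.
#' @param start_depth Initial height of the DNA end nearest the aperture (nm).
#' @param frame_interval Frame-saving cadence (ns).
#' @param seed Integer seed.
#' @param preset `"desk_scale"` or `"paper_scale"`; fills the remaining
#'   defaults.
#' @return An object of class `nj_sim_params`.
#' @export
sim_params <- function(timestep = NULL, temperature = 291, bias = 600,
                       equilibration_time = NULL, max_time = NULL,
                       post_eject_time = NULL, start_depth = NULL,
                       frame_interval = NULL, seed = 1,
                       preset = c("desk_scale", "paper_scale")) {
  preset <- match.arg(preset)
  d <- if (preset == "desk_scale") {
    list(timestep = 2e-3, equilibration_time = 50, max_time = 2500,
         post_eject_time = 500, start_depth = 18.5, frame_interval = 2)
  } else {
    list(timestep = 4e-5, equilibration_time = 75000, max_time = 3e5,
         post_eject_time = 5000, start_depth = 185, frame_interval = 100)
  }
  p <- list(
    timestep = timestep %||% d$timestep,
    temperature = temperature, bias = bias,
    equilibration_time = equilibration_time %||% d$equilibration_time,
    max_time = max_time %||% d$max_time,
    post_eject_time = post_eject_time %||% d$post_eject_time,
    start_depth = start_depth %||% d$start_depth,
    frame_interval = frame_interval %||% d$frame_interval,
    seed = as.integer(seed), preset = preset
  )
  stopifnot(p$timestep > 0, p$temperature > 0, p$start_depth > 0)
  class(p) <- "nj_sim_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Start-depth subgroups
#'
#' The published ensembles place the DNA end nearest the aperture in three
#' subgroups; at desk scale the depths are reduced with the geometry.
#'
#' @param preset `"desk_scale"` or `"paper_scale"`.
#' @return Numeric vector of three depths (nm).
#' @export
start_depth_groups <- function(preset = c("desk_scale", "paper_scale")) {
  preset <- match.arg(preset)
  if (preset == "paper_scale") c(100, 185, 270) else c(10, 18.5, 27)
}

#' One overdamped Brownian-dynamics step
#'
#' `x <- x + (D/kT) F dt + sqrt(2 D dt) xi` with `xi` standard normal per
#' coordinate. Exposed for calibration checks (free diffusion, drift,
#' trap variance); the production integrator in [run_translocation()] applies
#' the identical rule in compiled code.
#'
#' @param positions n x 3 matrix (nm).
#' @param forces n x 3 matrix (kcal/mol/nm).
#' @param D Diffusivity (nm^2/ns), scalar or per-particle vector.
#' @param dt Timestep (ns).
#' @param kT Thermal energy (kcal/mol).
#' @return Updated n x 3 position matrix.
#' @export
bd_step <- function(positions, forces, D, dt, kT = kT_kcal()) {
  if (any(!is.finite(forces))) stop("non-finite forces")
  n <- nrow(positions)
  positions + (D / kT) * forces * dt +
    sqrt(2 * D * dt) * matrix(stats::rnorm(3 * n), n, 3)
}

#' Trajectory object
#'
#' Time-stamped frames of all particle positions plus per-bead aperture
#' first-crossing times and run metadata.
#'
#' @param times Frame times (ns), strictly increasing.
#' @param frames n x 3 x n_frames array of positions (nm).
#' @param n_dna Number of DNA beads (first `n_dna` rows of each frame).
#' @param bp_per_bead Base pairs represented per bead.
#' @param crossing_ns Per-bead first time (ns) its z went below the aperture
#'   plane (NA if never).
#' @param completed Logical: all beads ejected before the step cap.
#' @param params The `nj_sim_params` used.
#' @param ... Further metadata stored on the object.
#' @export
trajectory <- function(times, frames, n_dna, bp_per_bead, crossing_ns,
                       completed, params, ...) {
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  dm <- dim(frames)
  if (length(dm) != 3 || dm[2] != 3 || dm[3] != length(times))
    stop("frames must be an n x 3 x n_frames array matching times")
  structure(list(times = times, frames = frames, n_dna = n_dna,
                 bp_per_bead = bp_per_bead, crossing_ns = crossing_ns,
                 completed = completed, params = params, ...),
            class = "nj_trajectory")
}

#' @exportS3Method base::print
print.nj_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames over %.1f ns, %d DNA beads + %d crowders\n",
              length(x$times), max(x$times), x$n_dna, dim(x$frames)[1] - x$n_dna))
  cat(sprintf("  ejection %s; %d/%d beads crossed\n",
              if (isTRUE(x$completed)) "complete" else "incomplete",
              sum(!is.na(x$crossing_ns)), x$n_dna))
  invisible(x)
}

# assemble per-particle parameter vectors and 2x2 pair tables
pair_tables <- function(dna, crowders) {
  cross <- if (is.null(crowders)) list(rmin_cd = 1, eps_cd = 0)
           else crowder_cross_pars(crowders, dna)
  rmin_cc <- if (is.null(crowders)) 1 else crowders$rmin_cc
  eps_cc <- if (is.null(crowders)) 0 else crowders$epsilon_cc
  rmin <- matrix(c(dna$bead_rmin, cross$rmin_cd, cross$rmin_cd, rmin_cc), 2, 2)
  eps <- matrix(c(dna$epsilon_self, cross$eps_cd, cross$eps_cd, eps_cc), 2, 2)
  # cutoffs: DNA-DNA purely repulsive (cut at Rmin); others 3 x Rmin
  cut <- matrix(c(dna$bead_rmin, 3 * cross$rmin_cd, 3 * cross$rmin_cd,
                  3 * rmin_cc), 2, 2)
  rep_only <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  list(rmin = rmin, eps = eps, cut = cut, rep_only = rep_only)
}

engine_call <- function(pos, n_dna, grids, dna, crowders, params, nsteps,
                        bias_on, record_crossings, frame_every,
                        post_eject_ns = Inf, forces_only = FALSE) {
  n <- nrow(pos)
  kT <- kT_kcal(params$temperature)
  charge <- c(rep(if (n_dna > 0) dna$charge_per_bead else 0, n_dna),
              rep(0, n - n_dna))
  Dvec <- c(rep(if (n_dna > 0) dna$bead_D else 0, n_dna),
            rep(if (is.null(crowders)) 0 else crowders$D, n - n_dna))
  pt <- pair_tables(dna %||% build_dna(100), crowders)
  bd_run_cpp(pos, n_dna,
             unclass(grids$steric_dna), unclass(grids$steric_crowder),
             unclass(grids$electrostatic), bias_on,
             charge * mv_e_to_kcal(), Dvec,
             if (n_dna > 0) dna$bond_stiffness else 0,
             if (n_dna > 0) dna$bond_rest_length else 1,
             if (n_dna > 0) dna$bending_stiffness else 0,
             pt$rmin, pt$eps, pt$cut, pt$rep_only,
             params$timestep, kT, nsteps, as.integer(frame_every),
             record_crossings,
             if (is.finite(post_eject_ns)) post_eject_ns else 1e18,
             0.5, 25L, 1.5, forces_only)
}

#' One-shot force evaluation of the full system
#'
#' Computes the forces the production engine would apply at the given
#' configuration (grid + bonded + pair terms, via the neighbour list). Used
#' to validate the neighbour-listed pair sum against an all-pairs reference.
#'
#' @param pos n x 3 positions; DNA beads first.
#' @param n_dna Number of DNA beads.
#' @param grids List from [build_system_grids()].
#' @param dna `nj_dna_model` (or NULL if no DNA).
#' @param crowders `nj_crowder_model` (or NULL).
#' @param params `nj_sim_params`.
#' @param bias_on Apply the electrostatic grid force.
#' @return n x 3 force matrix (kcal/mol/nm).
#' @export
system_forces <- function(pos, n_dna, grids, dna = NULL, crowders = NULL,
                          params = sim_params(), bias_on = TRUE) {
  engine_call(pos, n_dna, grids, dna, crowders, params, 0, bias_on,
              FALSE, 1L, forces_only = TRUE)$forces
}

#' Equilibrate-then-eject translocation run
#'
#' Protocol: stuff the DNA into the pipette with its leading end at
#' `params$start_depth`, place crowders (if a crowder model is given),
#' equilibrate with the bias off, then switch the bias on and integrate until
#' every DNA bead is below the aperture plane (plus `post_eject_time`) or
#' `max_time` is reached.
#'
#' @param geom An `nj_geometry`.
#' @param dna An `nj_dna_model`.
#' @param crowders An `nj_crowder_model`, or NULL for a crowder-free run.
#' @param params An `nj_sim_params`.
#' @param grids Optional pre-built grids from [build_system_grids()].
#' @return An `nj_trajectory`. Incomplete runs (cap reached before full
#'   ejection) are returned with `completed = FALSE`.
#' @export
run_translocation <- function(geom, dna, crowders = NULL,
                              params = sim_params(), grids = NULL) {
  if (is.null(grids)) grids <- build_system_grids(geom, bias = params$bias)
  set.seed(params$seed)
  state <- init_dna_in_pipette(dna, geom, params$start_depth)
  cpos <- if (is.null(crowders)) matrix(numeric(0), 0, 3)
          else place_crowders(geom, crowders$concentration)
  pos <- rbind(state$positions, cpos)
  n_dna <- dna$n_beads
  dt <- params$timestep
  fr_every <- max(1L, round(params$frame_interval / dt))

  eq_steps <- round(params$equilibration_time / dt)
  if (eq_steps > 0) {
    eq <- engine_call(pos, n_dna, grids, dna, crowders, params, eq_steps,
                      bias_on = FALSE, record_crossings = FALSE,
                      frame_every = eq_steps)
    pos <- eq$positions
  }

  prod_steps <- round(params$max_time / dt)
  run <- engine_call(pos, n_dna, grids, dna, crowders, params, prod_steps,
                     bias_on = TRUE, record_crossings = TRUE,
                     frame_every = fr_every,
                     post_eject_ns = params$post_eject_time)
  trajectory(times = run$times, frames = run$frames, n_dna = n_dna,
             bp_per_bead = dna$bp_per_bead, crossing_ns = run$crossing_ns,
             completed = isTRUE(run$ejected), params = params,
             eject_time = run$eject_time, warn_frac = run$warn_frac,
             geometry = geom, crowded = !is.null(crowders))
}

#' Base pairs having exited the pore by time t
#'
#' Counts base pairs whose bead has first crossed the aperture plane by
#' time `t` (production-time axis). Monotone nondecreasing in `t`.
#'
#' @param traj An `nj_trajectory`.
#' @param t Time (ns), vectorised.
#' @return Count(s) of base pairs.
#' @export
bp_exited <- function(traj, t) {
  cr <- traj$crossing_ns[!is.na(traj$crossing_ns)]
  vapply(t, function(tt) sum(cr <= tt), 0) * traj$bp_per_bead
}

#' Elapsed translocation time
#'
#' Time between the first and last base pair crossing the aperture plane.
#'
#' @param traj A completed `nj_trajectory`.
#' @return Time (ns).
#' @export
translocation_time <- function(traj) {
  if (!isTRUE(traj$completed))
    stop("translocation_time is undefined for an incomplete run")
  cr <- traj$crossing_ns
  max(cr) - min(cr)
}

# positions of frame i as an n x 3 matrix
frame_positions <- function(traj, i) {
  matrix(traj$frames[, , i], ncol = 3)
}
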