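#' SEM evaluation sub-grid
#'
#' The steric-exclusion-model current is integrated over a box around the
#' aperture, where essentially all of the series resistance (and hence the
#' sensitivity to particle occupancy) is concentrated. Voxels in fluid get
#' base factor 1, wall voxels 0.
#'
#' @param geom An `nj_geometry`.
#' @param lateral_halfwidth Half-width of the box in x and y (nm).
#' @param z_range Axial extent (nm), `c(below, above)` the aperture.
#' @param spacing Voxel spacing (nm).
#' @return An `nj_grid` of kind "mobility" holding the base (particle-free)
#'   factors.
#' @export
sem_base_grid <- function(geom, lateral_halfwidth = 12, z_range = c(-15, 25),
                          spacing = 1) {
  ax <- list(x = seq(-lateral_halfwidth, lateral_halfwidth, by = spacing),
             y = seq(-lateral_halfwidth, lateral_halfwidth, by = spacing),
             z = seq(z_range[1], z_range[2], by = spacing))
  g <- expand.grid(x = ax$x, y = ax$y, z = ax$z)
  fl <- is_fluid(geom, g$x, g$y, g$z)
  vals <- array(as.numeric(fl), lengths(ax))
  potential_grid(vapply(ax, `[`, 0, 1), spacing, vals, "mobility")
}

#' SEM mobility-factor parameters
#'
#' @param dna_enhancement Mobility factor at the DNA bead surface (default
#'   1.5); decays linearly to 1 at `dna_outer`. A stand-in profile for the
#'   ion-enhancement data around DNA in 170 mM KCl; ordering-style analyses
#'   are insensitive to its exact value.
#' @param dna_inner Radius (nm) inside which the full enhancement applies.
#' @param dna_outer Distance (nm) at which the DNA factor returns to 1.
#' @param crowder_inner,crowder_outer Crowder mobility ramp (nm): factor 0
#'   below inner, 1 above outer, linear between (defaults 2.5 and 4).
#' @param bulk_conductivity Bulk conductivity of 170 mM KCl (S/m).
#' @return List of SEM parameters.
#' @export
sem_params <- function(dna_enhancement = 1.5, dna_inner = 0.55,
                       dna_outer = 2, crowder_inner = 2.5,
                       crowder_outer = 4, bulk_conductivity = 2.0) {
  list(dna_enhancement = dna_enhancement, dna_inner = dna_inner,
       dna_outer = dna_outer, crowder_inner = crowder_inner,
       crowder_outer = crowder_outer, bulk_conductivity = bulk_conductivity)
}

#' Voxel ionic-mobility map for one configuration
#'
#' Per-voxel factor = wall mask x DNA enhancement (function of distance to
#' the nearest DNA bead) x crowder ramp (0 below `crowder_inner` nm from the
#' nearest crowder centre, 1 above `crowder_outer`, linear between).
#'
#' @param base An `nj_grid` from [sem_base_grid()].
#' @param dna_pos m x 3 DNA bead positions (nm) or NULL.
#' @param crowder_pos m x 3 crowder positions (nm) or NULL.
#' @param pars List from [sem_params()].
#' @return An `nj_grid` of kind "mobility".
#' @export
build_mobility_map <- function(base, dna_pos = NULL, crowder_pos = NULL,
                               pars = sem_params()) {
  empty <- matrix(numeric(0), 0, 3)
  vals <- sem_factor_cpp(unclass(base),
                         if (is.null(dna_pos)) empty else to_pos_matrix(dna_pos),
                         if (is.null(crowder_pos)) empty else to_pos_matrix(crowder_pos),
                         pars$dna_enhancement, pars$dna_inner, pars$dna_outer,
                         pars$crowder_inner, pars$crowder_outer)
  dim(vals) <- base$dim
  potential_grid(base$origin, base$spacing, vals, "mobility")
}

#' Ionic current from a mobility map (series-of-slabs)
#'
#' Per-axial-slab conductance `G_k = sigma * sum(factors) * dx * dy / dz`;
#' the current is `bias / sum(1/G_k)`. Monotone nondecreasing in every voxel
#' factor.
#'
#' @param map An `nj_grid` of mobility factors.
#' @param bias Applied bias (mV).
#' @param conductivity Bulk conductivity (S/m).
#' @return Current (pA).
#' @export
compute_current <- function(map, bias = 600, conductivity = 2.0) {
  slab <- colSums(matrix(map$values, prod(map$dim[1:2]), map$dim[3]))
  if (any(slab <= 0)) stop("blocked pore: a slab has zero total conductance")
  gk <- conductivity * 1e-9 * slab * map$spacing[1] * map$spacing[2] /
    map$spacing[3]
  bias / sum(1 / gk) * 1e9
}

#' Current time series of a trajectory
#'
#' Evaluates the SEM current for every stored frame.
#'
#' @param traj An `nj_trajectory`.
#' @param base An `nj_grid` from [sem_base_grid()].
#' @param pars List from [sem_params()].
#' @param bias Applied bias (mV); defaults to the trajectory's.
#' @return Data frame with `time_ns` and `current_pA`.
#' @export
current_trace_sem <- function(traj, base, pars = sem_params(), bias = NULL) {
  bias <- bias %||% traj$params$bias
  n <- dim(traj$frames)[1]
  cur <- sem_trace_cpp(unclass(base), traj$frames, traj$n_dna, n,
                       pars$dna_enhancement, pars$dna_inner, pars$dna_outer,
                       pars$crowder_inner, pars$crowder_outer,
                       bias, pars$bulk_conductivity)
  data.frame(time_ns = traj$times, current_pA = cur)
}

#' Open-pore baseline current
#'
#' Time-and-ensemble mean SEM current over DNA-free trajectories (crowders
#' only), used as the condition-matched denominator of enhancement traces.
#'
#' @param base An `nj_grid` from [sem_base_grid()].
#' @param trajectories List of >= 1 DNA-free `nj_trajectory` objects (>= 2
#'   for a standard-deviation estimate).
#' @param pars,bias As in [current_trace_sem()].
#' @return List with `mean_pA`, `sd_pA`, `n_frames`.
#' @export
open_pore_baseline <- function(base, trajectories, pars = sem_params(),
                               bias = 600) {
  if (length(trajectories) == 0) stop("no trajectories supplied")
  cur <- unlist(lapply(trajectories, function(tr)
    current_trace_sem(tr, base, pars, bias)$current_pA))
  list(mean_pA = mean(cur),
       sd_pA = if (length(cur) > 1) stats::sd(cur) else 0,
       n_frames = length(cur))
}

#' Current-enhancement trace I/I0
#'
#' @param traj An `nj_trajectory`.
#' @param baseline Open-pore baseline current (pA): a number or the list
#'   returned by [open_pore_baseline()]. Must be condition-matched (crowded
#'   baseline for crowded runs).
#' @param base,pars,bias As in [current_trace_sem()].
#' @return Data frame with `time_ns`, `current_pA`, `enhancement`.
#' @export
enhancement_trace <- function(traj, baseline, base, pars = sem_params(),
                              bias = NULL) {
  b <- if (is.list(baseline)) baseline$mean_pA else baseline
  if (!is.finite(b) || b <= 0) stop("baseline must be > 0")
  tr <- current_trace_sem(traj, base, pars, bias)
  tr$enhancement <- tr$current_pA / b
  tr
}

#' Crowder-only baseline run
#'
#' Simulates crowders with no DNA under the production conditions, for
#' estimating the open-pore (bulk) conductance of the crowded bath.
#'
#' @param geom An `nj_geometry`.
#' @param crowders An `nj_crowder_model`.
#' @param params An `nj_sim_params`; `max_time` is used as the run length.
#' @param grids Optional pre-built grids.
#' @return An `nj_trajectory` with `n_dna = 0`.
#' @export
run_baseline_simulation <- function(geom, crowders, params = sim_params(),
                                    grids = NULL) {
  if (is.null(grids)) grids <- build_system_grids(geom, bias = params$bias)
  set.seed(params$seed)
  pos <- place_crowders(geom, crowders$concentration)
  dt <- params$timestep
  fr_every <- max(1L, round(params$frame_interval / dt))
  run <- engine_call(pos, 0L, grids, NULL, crowders, params,
                     round(params$max_time / dt), bias_on = TRUE,
                     record_crossings = FALSE, frame_every = fr_every)
  trajectory(times = run$times, frames = run$frames, n_dna = 0L,
             bp_per_bead = 0, crossing_ns = numeric(0), completed = TRUE,
             params = params, geometry = geom, crowded = TRUE)
}
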