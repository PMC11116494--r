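#' Radius of gyration of the ejected DNA
#'
#' At each frame, the radius of gyration of the beads that have crossed the
#' aperture plane (z < 0), reported against elapsed time, base pairs exited,
#' and time since the last base pair exited (NA until ejection completes).
#'
#' @param traj An `nj_trajectory`.
#' @return Data frame with `time_ns`, `bp_exited`, `time_since_last_bp`,
#'   `rg_nm` (NA where no bead is ejected), `n_ejected`.
#' @export
ejected_rg_curve <- function(traj) {
  per_frame_ejected(traj, function(pos) radius_of_gyration(pos), "rg_nm")
}

#' Axial centre-of-mass distance of the ejected DNA
#'
#' Distance of the ejected beads' centre of mass from the aperture plane,
#' projected on the pore axis: `|mean(z)|`.
#'
#' @param traj An `nj_trajectory`.
#' @return Data frame with `time_ns`, `bp_exited`, `time_since_last_bp`,
#'   `com_distance_nm`, `n_ejected`.
#' @export
com_distance_curve <- function(traj) {
  per_frame_ejected(traj, function(pos) abs(mean(pos[, 3])), "com_distance_nm")
}

per_frame_ejected <- function(traj, fn, name) {
  nf <- length(traj$times)
  last_cross <- if (all(is.na(traj$crossing_ns))) NA_real_
                else max(traj$crossing_ns, na.rm = TRUE)
  out <- data.frame(time_ns = traj$times,
                    bp_exited = bp_exited(traj, traj$times),
                    time_since_last_bp = rep(NA_real_, nf),
                    val = rep(NA_real_, nf),
                    n_ejected = integer(nf))
  if (isTRUE(traj$completed)) {
    dtl <- traj$times - last_cross
    out$time_since_last_bp <- ifelse(dtl >= 0, dtl, NA_real_)
  }
  dna_idx <- seq_len(traj$n_dna)
  for (i in seq_len(nf)) {
    pos <- frame_positions(traj, i)[dna_idx, , drop = FALSE]
    ej <- pos[, 3] < 0
    out$n_ejected[i] <- sum(ej)
    if (any(ej)) out$val[i] <- fn(pos[ej, , drop = FALSE])
  }
  names(out)[names(out) == "val"] <- name
  out
}

#' Crowder count in the analysis cylinder below the aperture
#'
#' Counts crowder centres inside a cylinder coaxial with the pore and
#' immediately below the aperture: radial distance < `radius` and
#' `-height < z < 0`.
#'
#' @param traj An `nj_trajectory` containing crowders.
#' @param radius Cylinder radius (nm, default 15).
#' @param height Cylinder height (nm, default 30).
#' @return Data frame with `time_ns` and `count`.
#' @export
crowders_below_aperture <- function(traj, radius = 15, height = 30) {
  n <- dim(traj$frames)[1]
  if (n <= traj$n_dna) stop("trajectory contains no crowders")
  idx <- (traj$n_dna + 1):n
  counts <- vapply(seq_along(traj$times), function(i) {
    pos <- frame_positions(traj, i)[idx, , drop = FALSE]
    sum(pos[, 3] > -height & pos[, 3] < 0 &
          pos[, 1]^2 + pos[, 2]^2 < radius^2)
  }, 0L)
  data.frame(time_ns = traj$times, count = counts)
}

#' Pointwise ensemble mean and standard deviation of aligned curves
#'
#' Aligns per-run curves on a common axis and returns the pointwise mean and
#' sample (n-1) standard deviation. Time alignment interpolates linearly and
#' carries endpoints forward/backward; base-pair alignment resamples by
#' last-observation-carried-forward (base-pair exit counts are staircases).
#'
#' @param curves List of data frames, each with the axis column and a value
#'   column.
#' @param axis Name of the axis column (e.g. `"time_ns"` or `"bp_exited"`).
#' @param value Name of the value column.
#' @param grid Common axis grid; defaults to the union range on a regular
#'   grid of 200 points (time) or the integer bp grid (bp).
#' @param alignment `"time"` (linear interpolation) or `"bp"` (staircase
#'   LOCF).
#' @return List of class `nj_ensemble_summary` with `grid`, `mean`, `sd`,
#'   `n_runs`.
#' @export
ensemble_mean_sd <- function(curves, axis, value,
                             alignment = c("time", "bp"), grid = NULL) {
  alignment <- match.arg(alignment)
  if (length(curves) < 2) stop("need >= 2 runs for an ensemble summary")
  if (!all(vapply(curves, function(d) all(c(axis, value) %in% names(d)), TRUE)))
    stop("misaligned curves: missing '", axis, "' or '", value, "' column")
  if (is.null(grid)) {
    rng <- range(unlist(lapply(curves, function(d) range(d[[axis]], na.rm = TRUE))))
    grid <- if (alignment == "bp") seq(floor(rng[1]), ceiling(rng[2]))
            else seq(rng[1], rng[2], length.out = 200)
  }
  mat <- vapply(curves, function(d) {
    ok <- is.finite(d[[value]]) & is.finite(d[[axis]])
    x <- d[[axis]][ok]; y <- d[[value]][ok]
    if (alignment == "bp") {
      stats::approx(x, y, xout = grid, method = "constant", f = 0,
                    rule = 2, ties = list("ordered", function(v) v[length(v)]))$y
    } else {
      stats::approx(x, y, xout = grid, rule = 2, ties = mean)$y
    }
  }, numeric(length(grid)))
  structure(list(grid = grid,
                 mean = rowMeans(mat),
                 sd = apply(mat, 1, stats::sd),
                 n_runs = length(curves), axis = axis, value = value),
            class = "nj_ensemble_summary")
}

#' @exportS3Method base::print
print.nj_ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble summary of %s over %d runs (%d grid points on %s)\n",
              x$value, x$n_runs, length(x$grid), x$axis))
  invisible(x)
}

#' Per-run crowding summary scalars
#'
#' Extracts, from one completed translocation run, the scalars the crowding
#' comparison rests on: elapsed translocation time, final ejected-DNA radius
#' of gyration (mean over the last `tail_frames` frames), mean and peak
#' current enhancement during translocation, and (for crowded runs) the
#' crowder-cylinder counts before and during DNA transit.
#'
#' @param traj A completed `nj_trajectory`.
#' @param base An `nj_grid` from [sem_base_grid()] (NULL to skip currents).
#' @param baseline Condition-matched open-pore current (pA), for the
#'   enhancement columns.
#' @param pars SEM parameters.
#' @param tail_frames Number of final frames averaged for the final Rg
#'   (default 75, i.e. the last ~150 ns of the post-ejection relaxation
#'   window at the desk frame cadence).
#' @return One-row data frame.
#' @export
crowding_summary <- function(traj, base = NULL, baseline = NULL,
                             pars = sem_params(), tail_frames = 75) {
  out <- data.frame(
    crowded = isTRUE(traj$crowded),
    completed = isTRUE(traj$completed),
    translocation_ns = if (isTRUE(traj$completed)) translocation_time(traj)
                       else NA_real_
  )
  rgc <- ejected_rg_curve(traj)
  nf <- nrow(rgc)
  tail_idx <- seq(max(1, nf - tail_frames + 1), nf)
  out$final_rg_nm <- mean(rgc$rg_nm[tail_idx], na.rm = TRUE)
  out$final_com_nm <- mean(com_distance_curve(traj)$com_distance_nm[tail_idx],
                           na.rm = TRUE)
  out$mean_enhancement <- NA_real_
  out$peak_enhancement <- NA_real_
  out$cyl_pre <- NA_real_
  out$cyl_transit <- NA_real_
  cr <- traj$crossing_ns
  t0 <- suppressWarnings(min(cr, na.rm = TRUE))
  t1 <- suppressWarnings(max(cr, na.rm = TRUE))
  if (!is.null(base) && !is.null(baseline) && is.finite(t0)) {
    enh <- enhancement_trace(traj, baseline, base, pars)
    transit <- enh$time_ns >= t0 & enh$time_ns <= t1
    out$mean_enhancement <- mean(enh$enhancement[transit])
    out$peak_enhancement <- max(enh$enhancement)
  }
  if (isTRUE(traj$crowded) && is.finite(t0)) {
    cyl <- crowders_below_aperture(traj)
    out$cyl_pre <- mean(cyl$count[cyl$time_ns < t0])
    out$cyl_transit <- mean(cyl$count[cyl$time_ns >= t0 & cyl$time_ns <= t1])
  }
  out
}
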