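#' Asymmetric least squares baseline
#'
#' Tracks a slowly varying baseline through a trace containing sparse events
#' by minimising `sum(w_i (y_i - z_i)^2) + lambda * sum((d2 z)^2)` with
#' asymmetric weights re-estimated each iteration: samples on the event side
#' of the current baseline get weight `p`, the rest `1 - p` (Eilers-style
#' penalised smoothing). The residual noise is estimated robustly as
#' `1.4826 * MAD` of the residuals.
#'
#' @param trace An `nj_trace` (or numeric vector of currents, pA).
#' @param lam Smoothness penalty (default 1e9).
#' @param p Asymmetry (0 < p < 1, default 1e-3): the weight of samples above
#'   the baseline (below, for `polarity = -1`).
#' @param n_iter Reweighting iterations (default 10).
#' @param polarity `+1` if events are positive excursions, `-1` for
#'   blockades.
#' @return Object of class `nj_baseline`: `baseline` (pA), `noise_sd` (pA),
#'   `lambda`, `p`.
#' @export
als_baseline <- function(trace, lam = 1e9, p = 1e-3, n_iter = 10,
                         polarity = 1) {
  y <- if (inherits(trace, "nj_trace")) trace$current else as.numeric(trace)
  if (length(y) < 10) stop("trace too short (need >= 10 samples)")
  if (!all(is.finite(y))) stop("non-finite samples in trace")
  if (lam <= 0 || p <= 0 || p >= 1) stop("need lam > 0 and 0 < p < 1")
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lam * Matrix::crossprod(D)
  ctr <- stats::median(y) # centre the solve: exact for constant traces
  yc <- y - ctr
  w <- rep(1, n)
  z <- yc
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * yc))
    r <- polarity * (yc - z)
    w_new <- ifelse(r > 0, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  res <- yc - z
  # the asymmetric weights settle the smooth fit a couple of noise sd on the
  # non-event side; re-centre on the (event-robust) median residual so the
  # baseline tracks the noise mean
  z <- z + ctr + stats::median(res)
  res <- y - z
  structure(list(baseline = z,
                 noise_sd = 1.4826 * stats::mad(res, constant = 1),
                 lambda = lam, p = p, n_iter = it),
            class = "nj_baseline")
}

#' Threshold event detection
#'
#' Flags contiguous runs of samples whose absolute deviation from the
#' baseline exceeds `k_sigma` baseline-noise standard deviations, merges runs
#' separated by gaps of at most `merge_gap` samples, drops runs shorter than
#' `min_dwell` samples, and tabulates per-event dwell, peak amplitude and
#' equivalent charge.
#'
#' @param trace An `nj_trace`.
#' @param baseline_fit An `nj_baseline` from [als_baseline()] on the same
#'   trace (fitted with defaults if missing).
#' @param k_sigma Detection threshold in noise standard deviations
#'   (default 5).
#' @param min_dwell Minimum event length in samples (default 3).
#' @param merge_gap Maximum below-threshold gap merged into an event
#'   (samples, default 2).
#' @param noise_sd Optional override of the fitted noise sd (pA).
#' @return Object of class `nj_events`: data frame `events` (`start`, `end`,
#'   `dwell_ms`, `amplitude_pA`, `charge_fC`), and summary fields `count`,
#'   `threshold_pA`, `noise_sd`.
#' @export
detect_events <- function(trace, baseline_fit = NULL, k_sigma = 5,
                          min_dwell = 3, merge_gap = 2, noise_sd = NULL) {
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  if (is.null(baseline_fit)) baseline_fit <- als_baseline(trace)
  y <- trace$current
  if (length(baseline_fit$baseline) != length(y))
    stop("baseline was not fitted on this trace")
  sd_use <- noise_sd %||% baseline_fit$noise_sd
  if (!is.finite(sd_use) || sd_use <= 0)
    stop("noise sd is not positive; supply noise_sd explicitly")
  dev <- abs(y - baseline_fit$baseline)
  above <- dev > k_sigma * sd_use

  runs <- rle_runs(above)
  if (nrow(runs) > 1 && merge_gap > 0) {
    keep <- rep(TRUE, nrow(runs))
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - runs$end[i - 1] - 1 <= merge_gap && keep[i - 1]) {
        runs$end[i] <- max(runs$end[i], runs$end[i - 1])
        runs$start[i] <- runs$start[i - 1]
        keep[i - 1] <- FALSE
      }
    }
    runs <- runs[keep, , drop = FALSE]
  }
  runs <- runs[runs$end - runs$start + 1 >= min_dwell, , drop = FALSE]

  dt <- trace$sample_interval
  ev <- data.frame(start = runs$start, end = runs$end)
  ev$dwell_ms <- (ev$end - ev$start + 1) * dt * 1e3
  ev$amplitude_pA <- vapply(seq_len(nrow(ev)), function(i)
    max(dev[ev$start[i]:ev$end[i]]), 0)
  ev$charge_fC <- vapply(seq_len(nrow(ev)), function(i)
    event_charge_fc(y, baseline_fit$baseline, ev$start[i], ev$end[i], dt), 0)
  structure(list(events = ev, count = nrow(ev),
                 threshold_pA = k_sigma * sd_use, noise_sd = sd_use,
                 k_sigma = k_sigma),
            class = "nj_events")
}

#' @exportS3Method base::print
print.nj_events <- function(x, ...) {
  cat(sprintf("Event table: %d events (threshold %.2f pA = %g sigma, noise %.2f pA)\n",
              x$count, x$threshold_pA, x$k_sigma, x$noise_sd))
  if (x$count > 0)
    cat(sprintf("  median dwell %.2f ms, amplitude %.1f pA, charge %.1f fC\n",
                stats::median(x$events$dwell_ms),
                stats::median(x$events$amplitude_pA),
                stats::median(x$events$charge_fC)))
  invisible(x)
}

rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

event_charge_fc <- function(y, baseline, start, end, dt) {
  sum(abs(y[start:end] - baseline[start:end])) * dt * 1e3
  # pA * s = 1e-12 C; fC = 1e-15 C => factor 1e3
}

#' Equivalent charge of an event
#'
#' Time integral of the absolute current deviation from the baseline over
#' the event (sample sum x sampling interval), in femtocoulombs. For a
#' noiseless rectangular event this equals amplitude x dwell exactly
#' (100 pA over 1 ms = 100 fC).
#'
#' @param trace An `nj_trace`.
#' @param baseline Baseline (pA): an `nj_baseline`, a vector, or a scalar.
#' @param start,end Event sample indices (inclusive).
#' @return Charge (fC).
#' @export
equivalent_charge <- function(trace, baseline, start, end) {
  y <- trace$current
  if (start < 1 || end > length(y) || start > end)
    stop("event outside trace bounds")
  b <- if (inherits(baseline, "nj_baseline")) baseline$baseline else baseline
  b <- rep_len(b, length(y))
  event_charge_fc(y, b, start, end, trace$sample_interval)
}

#' Count delivered molecules
#'
#' The number of detected events: one event, one molecule. Events below the
#' detection threshold are missed, so the count can underestimate the true
#' number delivered.
#'
#' @param event_table An `nj_events` object (or its `events` data frame).
#' @return Integer count.
#' @export
count_molecules <- function(event_table) {
  if (inherits(event_table, "nj_events")) return(nrow(event_table$events))
  nrow(event_table)
}

#' Poisson arrival check on detected events
#'
#' Bins event start times into windows and reports the dispersion index
#' (variance/mean of per-window counts; 1 under Poisson arrivals) and a
#' chi-square goodness-of-fit p-value against the Poisson distribution with
#' the estimated rate.
#'
#' @param event_table An `nj_events`.
#' @param trace The trace the events came from (for the time axis).
#' @param window Window length (s).
#' @return List with `dispersion`, `p_value`, `counts`, `rate_per_s`.
#' @export
poisson_rate_check <- function(event_table, trace, window = 1) {
  ev <- if (inherits(event_table, "nj_events")) event_table$events else event_table
  if (nrow(ev) < 10) stop("need >= 10 events")
  t_start <- (ev$start - 1) * trace$sample_interval
  total <- length(trace$current) * trace$sample_interval
  breaks <- seq(0, total, by = window)
  if (length(breaks) < 6) stop("fewer than 5 windows; shorten the window")
  counts <- as.numeric(table(cut(t_start, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  m <- mean(counts)
  disp <- stats::var(counts) / m
  # chi-square GOF against Poisson(m), tails pooled to expected >= 1
  kmax <- max(counts)
  probs <- stats::dpois(0:kmax, m)
  probs[kmax + 1] <- probs[kmax + 1] + stats::ppois(kmax, m, lower.tail = FALSE)
  obs <- tabulate(counts + 1, nbins = kmax + 1)
  exp_n <- probs * length(counts)
  # pool adjacent cells until each group's expected count is >= 1
  grp <- integer(length(exp_n))
  g <- 1L; acc <- 0
  for (i in seq_along(exp_n)) {
    grp[i] <- g
    acc <- acc + exp_n[i]
    if (acc >= 1 && i < length(exp_n)) { g <- g + 1L; acc <- 0 }
  }
  if (acc < 1 && g > 1L) grp[grp == g] <- g - 1L # fold a light tail group back
  obs_p <- tapply(obs, grp, sum)
  exp_p <- tapply(exp_n, grp, sum)
  stat <- sum((obs_p - exp_p)^2 / exp_p)
  df <- max(1, length(obs_p) - 2)
  list(dispersion = disp,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       counts = counts, rate_per_s = m / window)
}

#' Zero-phase low-pass filter
#'
#' Optional pre-processing emulating the acquisition-chain analog filter:
#' a forward-backward (zero-phase) Butterworth low-pass at the given cutoff.
#' Off by default for synthetic traces.
#'
#' @param trace An `nj_trace`.
#' @param cutoff_kHz Cutoff frequency (kHz, default 10).
#' @param order Filter order (default 4).
#' @return Filtered `nj_trace`.
#' @export
lowpass_filter <- function(trace, cutoff_kHz = 10, order = 4) {
  if (!requireNamespace("signal", quietly = TRUE))
    stop("the 'signal' package is required for lowpass_filter()")
  fs <- 1 / trace$sample_interval
  wn <- cutoff_kHz * 1e3 / (fs / 2)
  if (wn >= 1) return(trace)
  bf <- signal::butter(order, wn)
  out <- signal::filtfilt(bf, trace$current)
  current_trace(out, trace$sample_interval, trace$voltage, cutoff_kHz)
}
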