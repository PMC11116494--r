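#' Current trace container
#'
#' A uniformly sampled ionic current trace.
#'
#' @param current Current samples (pA), finite.
#' @param sample_interval Sampling interval (s, default 1e-5: 100 kHz).
#' @param voltage Applied voltage (mV), metadata.
#' @param filter_kHz Analog filter cutoff (kHz), metadata.
#' @return Object of class `nj_trace`.
#' @export
current_trace <- function(current, sample_interval = 1e-5, voltage = -500,
                          filter_kHz = 10) {
  if (!all(is.finite(current))) stop("trace must be finite")
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  structure(list(current = as.numeric(current),
                 sample_interval = sample_interval,
                 voltage = voltage, filter_kHz = filter_kHz),
            class = "nj_trace")
}

#' @exportS3Method base::print
print.nj_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples at %g us (%.3f s), mean %.1f pA\n",
              length(x$current), x$sample_interval * 1e6,
              length(x$current) * x$sample_interval, mean(x$current)))
  invisible(x)
}

#' Event-population presets
#'
#' Amplitude/dwell distributions qualitatively emulating the translocation
#' event populations seen when ejecting dsDNA into a plain electrolyte
#' ("pbs_like": smaller, faster events, equivalent charge under 100 fC) and
#' into a crowded bath or cell ("crowded_like": larger and longer events,
#' charge around 200 fC).
#'
#' @param population `"pbs_like"` or `"crowded_like"`.
#' @return List with `amplitude` (truncated-normal mean/sd, pA) and `dwell`
#'   (log-normal meanlog/sdlog of the dwell in seconds).
#' @export
event_population <- function(population = c("pbs_like", "crowded_like")) {
  population <- match.arg(population)
  if (population == "pbs_like") {
    list(amplitude = list(mean = 60, sd = 15),
         dwell = list(meanlog = log(1.2e-3), sdlog = 0.45))
  } else {
    list(amplitude = list(mean = 110, sd = 25),
         dwell = list(meanlog = log(1.8e-3), sdlog = 0.70))
  }
}

#' Synthetic ionic current trace with planted translocation events
#'
#' Baseline + linear drift + white Gaussian noise + planted event pulses.
#' Event arrivals are Poisson with the given rate; amplitudes are
#' positive-truncated normal; dwells are log-normal. Pulse shapes are
#' top-hats with exponential (biexponential overall) edges, or exact
#' rectangles. Ground truth is returned alongside the trace.
#'
#' @param duration Trace length (s).
#' @param baseline Baseline current (pA).
#' @param drift Baseline drift (pA/s).
#' @param noise_sd White noise standard deviation (pA).
#' @param event_rate Mean event rate (1/s).
#' @param amplitude List with `mean`, `sd` (pA).
#' @param dwell List with `meanlog`, `sdlog` (log-seconds).
#' @param seed Integer seed (NULL: current RNG state).
#' @param sample_interval Sampling interval (s).
#' @param polarity `+1` for conductive (positive) events, `-1` for blockades.
#' @param shape `"biexp"` (default) or `"rect"`.
#' @param edge_tau Edge time constant for `"biexp"` (s).
#' @param allow_overlap Permit overlapping events (default FALSE: overlapping
#'   draws are re-placed, then dropped after 200 attempts).
#' @return List with `trace` (an `nj_trace`) and `truth` (data frame:
#'   `start`, `end` sample indices, `amplitude_pA`, `dwell_ms`) plus `count`.
#' @export
generate_trace <- function(duration = 5, baseline = 500, drift = 0,
                           noise_sd = 6, event_rate = 5,
                           amplitude = list(mean = 60, sd = 15),
                           dwell = list(meanlog = log(1.2e-3), sdlog = 0.45),
                           seed = NULL, sample_interval = 1e-5,
                           polarity = 1, shape = c("biexp", "rect"),
                           edge_tau = 3e-5, allow_overlap = FALSE) {
  shape <- match.arg(shape)
  if (noise_sd < 0 || event_rate < 0) stop("rates and sds must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / sample_interval)
  tt <- (seq_len(n) - 1) * sample_interval
  y <- baseline + drift * tt
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)

  n_ev <- stats::rpois(1, event_rate * duration)
  starts <- integer(0); ends <- integer(0); amps <- numeric(0); dws <- numeric(0)
  occupied <- logical(n)
  for (k in seq_len(n_ev)) {
    for (attempt in 1:200) {
      dw <- stats::rlnorm(1, dwell$meanlog, dwell$sdlog)
      len <- max(1L, round(dw / sample_interval))
      if (len >= n) stop("dwell longer than trace")
      s <- sample.int(n - len, 1)
      e <- s + len - 1L
      if (allow_overlap || !any(occupied[s:e])) break
      if (attempt == 200) s <- NA_integer_
    }
    if (is.na(s)) next
    a <- -1
    while (a <= 0) a <- stats::rnorm(1, amplitude$mean, amplitude$sd)
    occupied[s:e] <- TRUE
    pulse <- rep(a, e - s + 1L)
    if (shape == "biexp" && edge_tau > 0) {
      tl <- (0:(e - s)) * sample_interval
      rise <- 1 - exp(-(tl + sample_interval) / edge_tau)
      fall <- rev(rise)
      pulse <- a * pmin(rise, fall) / max(pmin(rise, fall))
    }
    y[s:e] <- y[s:e] + polarity * pulse
    starts <- c(starts, s); ends <- c(ends, e); amps <- c(amps, a)
    dws <- c(dws, (e - s + 1L) * sample_interval * 1e3)
  }
  ord <- order(starts)
  truth <- data.frame(start = starts[ord], end = ends[ord],
                      amplitude_pA = amps[ord], dwell_ms = dws[ord])
  list(trace = current_trace(y, sample_interval),
       truth = truth, count = nrow(truth))
}

#' Current trace from a SEM enhancement trace
#'
#' Resamples a simulated enhancement trace onto a uniform acquisition clock,
#' scales to pA by the open-pore baseline, and adds measurement noise.
#' Bridges the coarse-grained simulator to the event detector.
#'
#' @param enh Data frame with `time_ns` and `enhancement` (from
#'   [enhancement_trace()]).
#' @param baseline_pA Open-pore current used for scaling (pA).
#' @param noise_sd Added white noise (pA).
#' @param sample_interval Output sampling interval (s).
#' @param time_scale Seconds of output time per ns of simulation time
#'   (default 1e-9: real time).
#' @param seed Optional seed for the noise.
#' @return An `nj_trace`.
#' @export
trace_from_sem <- function(enh, baseline_pA, noise_sd = 0,
                           sample_interval = 1e-5, time_scale = 1e-9,
                           seed = NULL) {
  if (nrow(enh) == 0) stop("empty enhancement trace")
  if (!is.null(seed)) set.seed(seed)
  t_s <- enh$time_ns * time_scale
  out_t <- seq(min(t_s), max(t_s), by = sample_interval)
  y <- stats::approx(t_s, enh$enhancement * baseline_pA, xout = out_t,
                     rule = 2)$y
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  current_trace(y, sample_interval)
}

#' Write / read a two-column trace file
#'
#' Plain-text exchange format: `time_s, current_pA` (CSV or TSV by
#' extension).
#'
#' @param trace An `nj_trace`.
#' @param path Output file (.csv or .tsv).
#' @export
write_trace <- function(trace, path) {
  d <- data.frame(time_s = (seq_along(trace$current) - 1) * trace$sample_interval,
                  current_pA = trace$current)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param ... Passed to [current_trace()] (voltage, filter metadata).
#' @export
read_trace <- function(path, ...) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE)
  if (ncol(d) < 2) stop("expected a two-column time/current table")
  dt <- diff(d[[1]])
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("non-uniform sampling")
  current_trace(d[[2]], dt[1], ...)
}
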