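test_that("ALS baseline reproduces a constant and a drifting baseline", {
  tr <- current_trace(rep(250, 2000))
  fit <- als_baseline(tr)
  expect_lt(max(abs(fit$baseline - 250)), 1e-6)

  set.seed(15)
  n <- 50000
  dt <- 1e-5
  tt <- (seq_len(n) - 1) * dt
  y <- 400 + 100 * tt / max(tt) + stats::rnorm(n, 0, 2)
  fit2 <- als_baseline(current_trace(y, dt))
  ols <- stats::fitted(stats::lm(y ~ tt))
  rms <- sqrt(mean((fit2$baseline - ols)^2))
  expect_lt(rms / diff(range(ols)), 0.01)
  expect_equal(fit2$noise_sd, 2, tolerance = 0.1)
  expect_error(als_baseline(current_trace(rep(1, 5))), "short")
  expect_error(als_baseline(tr, lam = -1), "lam")
})

test_that("a large event does not drag the ALS baseline", {
  set.seed(16)
  n <- 20000
  sd0 <- 3
  y <- 500 + stats::rnorm(n, 0, sd0)
  y[8000:9000] <- y[8000:9000] + 150
  fit <- als_baseline(current_trace(y))
  expect_lt(max(abs(fit$baseline[8000:9000] - 500)), 3 * sd0)
})

test_that("pure Gaussian noise yields zero events at the 5-sigma threshold", {
  set.seed(17)
  tr <- current_trace(600 + stats::rnorm(1e5, 0, 4))
  ev <- detect_events(tr, als_baseline(tr), k_sigma = 5, min_dwell = 3)
  expect_identical(ev$count, 0L)
  expect_error(detect_events(tr, k_sigma = 0), "k_sigma")
})

test_that("planted events are recovered with faithful metrics", {
  g <- generate_trace(duration = 2, baseline = 500, noise_sd = 5,
                      event_rate = 5, seed = 18, shape = "rect",
                      amplitude = list(mean = 50, sd = 5),
                      dwell = list(meanlog = log(1e-3), sdlog = 0.3))
  fit <- als_baseline(g$trace)
  ev <- detect_events(g$trace, fit)
  expect_identical(ev$count, g$count)
  # single high-SNR event: amplitude within 10%
  g1 <- generate_trace(duration = 0.5, baseline = 500, noise_sd = 5,
                       event_rate = 4, seed = 33, shape = "rect",
                       amplitude = list(mean = 50, sd = 1e-6),
                       dwell = list(meanlog = log(2e-3), sdlog = 1e-6))
  ev1 <- detect_events(g1$trace, als_baseline(g1$trace))
  expect_identical(ev1$count, g1$count)
  expect_gt(ev1$count, 0)
  # peak amplitude is a max statistic: unbiased from below, inflated by at
  # most ~3 noise sd from above
  expect_true(all(ev1$events$amplitude_pA > 0.9 * 50))
  expect_true(all(ev1$events$amplitude_pA < 50 + 4 * 5))
  # exact on a noiseless rectangle
  g0 <- generate_trace(duration = 0.2, baseline = 500, noise_sd = 0,
                       event_rate = 20, seed = 34, shape = "rect",
                       amplitude = list(mean = 50, sd = 1e-9),
                       dwell = list(meanlog = log(2e-3), sdlog = 1e-6))
  ev0 <- detect_events(g0$trace, noise_sd = 1,
                       baseline_fit = structure(list(
                         baseline = rep(500, length(g0$trace$current)),
                         noise_sd = 1), class = "nj_baseline"))
  expect_gt(ev0$count, 0)
  expect_equal(ev0$events$amplitude_pA, rep(50, ev0$count), tolerance = 1e-9)
})

test_that("the detector is polarity-symmetric and threshold-monotone", {
  g <- generate_trace(duration = 1, baseline = 500, noise_sd = 5,
                      event_rate = 8, seed = 19)
  fit <- als_baseline(g$trace)
  ev_pos <- detect_events(g$trace, fit)
  neg <- current_trace(-g$trace$current, g$trace$sample_interval)
  fit_neg <- als_baseline(neg, polarity = -1)
  ev_neg <- detect_events(neg, fit_neg)
  expect_equal(ev_neg$events, ev_pos$events, tolerance = 1e-9)
  # monotonicity on clean, well-separated events (no near-threshold
  # fragmentation: rectangular pulses far above every tested threshold)
  gm <- generate_trace(duration = 2, baseline = 500, noise_sd = 5,
                       event_rate = 6, seed = 20, shape = "rect",
                       amplitude = list(mean = 100, sd = 5),
                       dwell = list(meanlog = log(1e-3), sdlog = 0.3))
  fitm <- als_baseline(gm$trace)
  counts <- vapply(c(4, 5, 6, 7, 8, 12), function(k)
    detect_events(gm$trace, fitm, k_sigma = k)$count, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("equivalent charge is exact for rectangles and halves for triangles", {
  dt <- 1e-5
  n <- 2000
  y <- rep(0, n)
  y[501:600] <- 100 # 100 samples at 100 pA: dwell 1 ms
  tr <- current_trace(y, dt)
  expect_equal(equivalent_charge(tr, 0, 501, 600), 100)
  expect_equal(equivalent_charge(tr, 0, 101, 200), 0)
  # symmetric triangle, peak 100, m = 50 samples each side: 50 fC
  m <- 50
  y2 <- rep(0, n)
  y2[1000 + (-m:m)] <- 100 * (1 - abs(-m:m) / m)
  tr2 <- current_trace(y2, dt)
  expect_equal(equivalent_charge(tr2, 0, 1000 - m, 1000 + m), 50)
  expect_error(equivalent_charge(tr2, 0, 0, 10), "bounds")
})

test_that("molecule counts add over disjoint traces and track the event table", {
  g1 <- generate_trace(duration = 1, event_rate = 6, seed = 21, noise_sd = 4,
                       amplitude = list(mean = 80, sd = 10))
  g2 <- generate_trace(duration = 1, event_rate = 6, seed = 22, noise_sd = 4,
                       amplitude = list(mean = 80, sd = 10))
  e1 <- detect_events(g1$trace, als_baseline(g1$trace))
  e2 <- detect_events(g2$trace, als_baseline(g2$trace))
  expect_identical(count_molecules(e1), e1$count)
  expect_identical(count_molecules(rbind(e1$events, e2$events)),
                   e1$count + e2$count)
  expect_identical(count_molecules(e1$events[0, ]), 0L)
})

test_that("the dispersion index separates Poisson, periodic and clustered arrivals", {
  tr <- current_trace(rep(0, 1e5)) # 1 s at 10 us
  mk <- function(starts) data.frame(start = starts, end = starts + 1)
  set.seed(23)
  pois <- sort(sample.int(99000, 400))
  chk <- poisson_rate_check(mk(pois), tr, window = 0.01)
  expect_gt(chk$dispersion, 0.7)
  expect_lt(chk$dispersion, 1.3)
  periodic <- seq(500, 99000, by = 250)
  chk2 <- poisson_rate_check(mk(periodic), tr, window = 0.01)
  expect_lt(chk2$dispersion, 0.5)
  clustered <- 5000 + 0:199
  chk3 <- poisson_rate_check(mk(clustered), tr, window = 0.01)
  expect_gt(chk3$dispersion, 10)
  expect_error(poisson_rate_check(mk(1:5), tr), ">= 10 events")
  expect_error(poisson_rate_check(mk(pois), tr, window = 0.5), "windows")
})

test_that("crowded-like synthetic events carry more equivalent charge than PBS-like ones", {
  med_charge <- function(pop, seed) {
    pars <- event_population(pop)
    g <- generate_trace(duration = 10, baseline = 500, noise_sd = 5,
                        event_rate = 5, seed = seed,
                        amplitude = pars$amplitude, dwell = pars$dwell)
    ev <- detect_events(g$trace, als_baseline(g$trace))
    stats::median(ev$events$charge_fC)
  }
  expect_gt(med_charge("crowded_like", 25), med_charge("pbs_like", 25))
})
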