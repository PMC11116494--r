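# small, fast system reused by the engine tests
mini_system <- function() {
  geom <- pore_geometry(pipette_length = 50, bath_width = 40, bath_depth = 32,
                        analysis_cylinder = c(radius = 15, height = 30))
  dna <- build_dna(50) # 10 beads, 17 nm contour
  grids <- build_system_grids(geom)
  list(geom = geom, dna = dna, grids = grids)
}

test_that("bd_step leaves particles in place in the zero-force, zero-temperature limit", {
  pos <- matrix(stats::rnorm(30), 10, 3)
  out <- bd_step(pos, matrix(0, 10, 3), D = 0, dt = 1e-3)
  expect_identical(out, pos)
  expect_error(bd_step(pos, matrix(NaN, 10, 3), 0.1, 1e-3), "finite")
})

test_that("identical seed and parameters give bitwise-identical trajectories", {
  s <- mini_system()
  p <- sim_params(seed = 77, start_depth = 6, max_time = 10,
                  equilibration_time = 2, post_eject_time = 2)
  t1 <- run_translocation(s$geom, s$dna, NULL, p, s$grids)
  t2 <- run_translocation(s$geom, s$dna, NULL, p, s$grids)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$crossing_ns, t2$crossing_ns)
})

test_that("zero bias stalls the chain; full bias ejects it with sane bookkeeping", {
  s <- mini_system()
  p0 <- sim_params(seed = 5, bias = 0, start_depth = 6, max_time = 30,
                   equilibration_time = 2)
  g0 <- build_system_grids(s$geom, bias = 0)
  stall <- run_translocation(s$geom, s$dna, NULL, p0, g0)
  expect_false(stall$completed)
  expect_error(translocation_time(stall), "incomplete")

  p <- sim_params(seed = 5, start_depth = 6, max_time = 400,
                  equilibration_time = 5, post_eject_time = 10)
  tr <- run_translocation(s$geom, s$dna, NULL, p, s$grids)
  expect_true(tr$completed)
  expect_true(all(is.finite(tr$crossing_ns)))
  expect_gt(translocation_time(tr), 0)
  expect_identical(bp_exited(tr, 0), 0)
  expect_identical(bp_exited(tr, max(tr$times)), s$dna$n_bp)
  curve <- bp_exited(tr, tr$times)
  expect_true(all(diff(curve) >= 0))
  expect_lt(tr$warn_frac, 1e-3)
  # no wall penetration beyond 10 kT anywhere in the run
  kT <- kT_kcal()
  worst <- max(vapply(seq_along(tr$times), function(i) {
    pos <- tr$frames[, , i]
    max(grid_value(s$grids$steric_dna, pos))
  }, 0))
  expect_lt(worst, 10 * kT)
  # chain integrity maintained to the final frame
  expect_silent(polymer_state(tr$frames[, , length(tr$times)], s$dna))
})

test_that("trajectory bookkeeping matches a per-frame recount on a planted staircase", {
  tr <- toy_trajectory(n_dna = 4, nf = 11, dt = 1, z0 = c(2.5, 4.5, 6.5, 8.5),
                       speed = 1, bp_per_bead = 5)
  expect_identical(bp_exited(tr, 0), 0)
  # recount oracle: beads strictly below the plane per frame
  for (i in seq_along(tr$times)) {
    recount <- sum(tr$frames[, 3, i] < 0) * tr$bp_per_bead
    expect_identical(bp_exited(tr, tr$times[i]), recount)
  }
  expect_equal(translocation_time(tr), 6) # crossings at 2.5 ... 8.5
})

test_that("translocation_time is the first-to-last crossing gap and rejects disorder", {
  tr <- toy_trajectory(n_dna = 2, nf = 60, dt = 1, z0 = c(1.5, 51.5), speed = 1)
  expect_equal(translocation_time(tr), 50)
  expect_error(
    trajectory(times = c(0, 2, 1), frames = array(0, c(1, 3, 3)), n_dna = 1,
               bp_per_bead = 5, crossing_ns = NA_real_, completed = FALSE,
               params = sim_params()),
    "strictly increasing")
})

test_that("a bead in a harmonic trap satisfies equipartition", {
  set.seed(31)
  kT <- kT_kcal()
  kappa <- 10
  D <- 0.18
  dt <- 1e-3
  n_rep <- 200
  pos <- matrix(0, n_rep, 3)
  burn <- 2000
  acc <- 0; nacc <- 0
  for (step in 1:22000) {
    pos <- bd_step(pos, -kappa * pos, D, dt, kT)
    if (step > burn && step %% 20 == 0) {
      acc <- acc + sum(pos^2); nacc <- nacc + length(pos)
    }
  }
  expect_equal(acc / nacc, kT / kappa, tolerance = 0.05)
})
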