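# free-standing uniform mobility box (all fluid)
uniform_base <- function(nx = 21, nz = 30, spacing = 1) {
  potential_grid(c(-(nx - 1) / 2 * spacing, -(nx - 1) / 2 * spacing, 0),
                 spacing, array(1, c(nx, nx, nz)), "mobility")
}

test_that("mobility factors follow the crowder ramp and DNA profile", {
  base <- uniform_base()
  pars <- sem_params()
  crw <- matrix(c(0, 0, 10), 1, 3)
  m <- build_mobility_map(base, crowder_pos = crw, pars = pars)
  at <- function(map, p) grid_value(map, p)
  expect_equal(at(m, c(0, 0, 12)), 0)          # 2.0 nm from the centre
  expect_equal(at(m, c(0, 0, 13.25)), 0.5)     # midpoint of the 2.5-4 ramp
  expect_equal(at(m, c(0, 0, 20)), 1)          # bulk
  # DNA enhancement: > 1 near a bead, 1 far away
  d <- build_mobility_map(base, dna_pos = matrix(c(0, 0, 10), 1, 3), pars = pars)
  expect_equal(at(d, c(0, 0, 10)), pars$dna_enhancement)
  expect_gt(at(d, c(0, 0, 11.5)), 1)
  expect_equal(at(d, c(0, 0, 15)), 1)
  # no particles at all: map equals the base exactly
  e <- build_mobility_map(base, NULL, NULL, pars)
  expect_identical(e$values, base$values)
})

test_that("slab-series current reproduces Ohm's law for a uniform cylinder", {
  spacing <- 0.5
  nx <- 65; nz <- 40; a <- 12; L <- nz * spacing
  ax <- (seq_len(nx) - (nx + 1) / 2) * spacing
  disc <- outer(ax, ax, function(x, y) as.numeric(x^2 + y^2 < a^2))
  vals <- array(rep(disc, nz), c(nx, nx, nz))
  map <- potential_grid(c(ax[1], ax[1], 0), spacing, vals, "mobility")
  sigma <- 2; bias <- 600
  got <- compute_current(map, bias, sigma)
  want <- bias * 1e-3 * (sigma * 1e-9 * pi * a^2 / L) * 1e12
  expect_equal(got, want, tolerance = 0.02)
})

test_that("two-section cylinder matches the analytic series-resistor formula", {
  spacing <- 1; nx <- 41
  ax <- (seq_len(nx) - (nx + 1) / 2) * spacing
  disc <- function(a) outer(ax, ax, function(x, y) as.numeric(x^2 + y^2 < a^2))
  n1 <- 12; n2 <- 20
  vals <- array(c(rep(disc(6), n1), rep(disc(14), n2)), c(nx, nx, n1 + n2))
  map <- potential_grid(c(ax[1], ax[1], 0), spacing, vals, "mobility")
  sigma <- 2; bias <- 600
  A1 <- sum(disc(6)); A2 <- sum(disc(14)) # voxelised areas, nm^2
  R <- n1 / (sigma * 1e-9 * A1) + n2 / (sigma * 1e-9 * A2)
  want <- bias * 1e-3 / R * 1e12
  expect_equal(compute_current(map, bias, sigma), want, tolerance = 1e-6)
})

test_that("current is monotone in voxel factors and errors on a blocked slab", {
  base <- uniform_base(11, 8)
  i0 <- compute_current(base)
  up <- base
  up$values[500] <- 1.6
  expect_gt(compute_current(up), i0)
  blocked <- base
  v <- array(blocked$values, blocked$dim)
  v[, , 4] <- 0
  blocked$values <- as.numeric(v)
  expect_error(compute_current(blocked), "blocked")
})

test_that("a DNA rod with an enhancing profile raises the current above the open pore", {
  geom <- pore_geometry()
  base <- sem_base_grid(geom)
  pars <- sem_params()
  i0 <- compute_current(build_mobility_map(base, NULL, NULL, pars))
  rod <- cbind(0, 0, seq(-8, 8, by = 1.7))
  i1 <- compute_current(build_mobility_map(base, rod, NULL, pars))
  expect_gt(i1, i0)
  # crowders near the aperture depress the current; removing them restores it
  set.seed(8)
  crw <- cbind(stats::runif(30, -10, 10), stats::runif(30, -10, 10),
               stats::runif(30, -14, -1))
  i_crw <- compute_current(build_mobility_map(base, NULL, crw, pars))
  expect_lt(i_crw, i0)
  near <- crw[, 1]^2 + crw[, 2]^2 < 36 & crw[, 3] > -8
  i_disp <- compute_current(build_mobility_map(base, NULL,
                                               crw[!near, , drop = FALSE], pars))
  expect_gt(i_disp, i_crw)
})

test_that("compiled trace evaluation equals the per-frame R route", {
  geom <- pore_geometry()
  base <- sem_base_grid(geom)
  pars <- sem_params()
  set.seed(12)
  crw <- cbind(stats::runif(40, -11, 11), stats::runif(40, -11, 11),
               stats::runif(40, -14, -2))
  tr <- toy_trajectory(n_dna = 5, n_crw = 40, nf = 10, dt = 2,
                       z0 = seq(4.5, 12.5, by = 2), speed = 0.5,
                       crw_pos = crw)
  fast <- current_trace_sem(tr, base, pars, bias = 600)
  slow <- vapply(seq_along(tr$times), function(i) {
    pos <- tr$frames[, , i]
    compute_current(build_mobility_map(base, pos[1:5, , drop = FALSE],
                                       pos[6:45, , drop = FALSE], pars),
                    600, pars$bulk_conductivity)
  }, 0)
  expect_equal(fast$current_pA, slow, tolerance = 1e-10)
})

test_that("open-pore baseline statistics and particle-free enhancement behave", {
  geom <- pore_geometry()
  base <- sem_base_grid(geom)
  pars <- sem_params()
  tr <- toy_trajectory(n_dna = 0, n_crw = 3, nf = 4, dt = 1,
                       z0 = numeric(0),
                       crw_pos = cbind(c(5, -6, 2), c(0, 3, -4), c(-5, -9, -12)))
  tr$n_dna <- 0L
  bl <- open_pore_baseline(base, list(tr), pars)
  expect_equal(bl$sd_pA, 0) # identical frames
  expect_equal(bl$mean_pA,
               compute_current(build_mobility_map(base, NULL, tr$frames[, , 1],
                                                  pars), 600,
                               pars$bulk_conductivity))
  expect_error(open_pore_baseline(base, list()), "no trajectories")
  # DNA-free, crowder-free trace: enhancement identically 1
  empty <- toy_trajectory(n_dna = 1, n_crw = 0, nf = 5, dt = 1, z0 = 100,
                          speed = 0)
  i0 <- compute_current(build_mobility_map(base, NULL, NULL, pars), 600,
                        pars$bulk_conductivity)
  enh <- enhancement_trace(empty, i0, base, pars, bias = 600)
  expect_equal(enh$enhancement, rep(1, 5), tolerance = 1e-12)
  expect_error(enhancement_trace(empty, 0, base, pars), "baseline")
})
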