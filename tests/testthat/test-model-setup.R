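test_that("geometry validation catches unusable configurations", {
  expect_error(pore_geometry(aperture_diameter = 0), "aperture")
  expect_error(pore_geometry(spacing = 4), "resolve the aperture")
  expect_error(pore_geometry(cone_half_angle = 0), "widen")
  expect_error(pore_geometry(bath_width = 20), "cylinder|cone")
  expect_error(tiny_geometry(depth = 2), "cylinder")
})

test_that("steric grid is zero in fluid, harmonic in the wall, and matches the brute-force distance oracle", {
  geom <- tiny_geometry()
  g <- build_steric_grid(geom, k = 2)
  vals <- array(g$values, g$dim)
  fluid <- vals == 0
  expect_true(any(fluid))
  expect_true(all(vals[!fluid] > 0))
  # deep-bath voxel is fluid (value 0); a far outside-wall voxel is penalised
  expect_identical(grid_value(g, c(0, 0, -3)), 0)
  d <- brute_force_wall_distance(g)
  expected <- 0.5 * 2 * (d * 10)^2 # d in angstrom, k = 2 kcal/mol/A^2
  expect_equal(vals, expected, tolerance = 1e-12)
  # wall voxel one spacing from fluid: d = 1 nm = 10 A -> 1/2*2*100 kcal/mol
  expect_true(any(abs(vals[!fluid] - 100) < 1e-9))
})

test_that("steric grid construction rejects too-coarse spacing", {
  geom <- tiny_geometry()
  expect_error(build_steric_grid(geom, spacing = 3), "spacing")
})

test_that("crowder steric kernel is normalised and the grid vanishes in deep fluid", {
  k <- nanoject:::ramp_kernel_cpp(rep(1, 3), 2.5, 4.5, TRUE)
  expect_equal(sum(k$w), 1, tolerance = 1e-6)
  geom <- tiny_geometry(width = 22, depth = 10, pip_len = 8)
  g <- build_crowder_steric_grid(geom, kernel_inner = 1, kernel_outer = 2.5)
  expect_true(all(g$values >= 0))
  # bath centre, farther than kernel_outer + wall extent from any wall
  expect_lt(grid_value(g, c(0, 0, -5)), 1e-9)
  expect_error(build_crowder_steric_grid(geom, kernel_inner = 3,
                                         kernel_outer = 2), "kernel_inner")
  expect_error(build_crowder_steric_grid(geom, kernel_outer = 12), "kernel")
})

test_that("convolution of an isolated penalty voxel reproduces the scaled kernel profile", {
  dims <- c(16, 16, 16)
  src <- array(0, dims)
  src[8, 8, 8] <- 10
  got <- nanoject:::convolve_ramp_cpp(as.numeric(src), as.integer(dims),
                                      rep(1, 3), 1.5, 3.5, TRUE, 0)
  want <- direct_ramp_convolution(src, dims, 1, 1.5, 3.5, oob = 0)
  expect_equal(array(got, dims), want, tolerance = 1e-12)
})

test_that("electrostatic grid drops the full bias, concentrated at the aperture, with ejecting polarity", {
  geom <- pore_geometry()
  for (sp in c(1, 0.5)) {
    g <- build_electrostatic_grid(geom, bias = 600, spacing = sp)
    drop <- grid_value(g, c(0, 0, geom$pipette_length)) -
      grid_value(g, c(0, 0, -geom$bath_box[3]))
    expect_equal(abs(drop), 600, tolerance = 0.01 * 600)
    # >= 50% of the drop within 5 aperture diameters of the aperture plane
    dz <- 5 * geom$aperture_diameter
    near <- abs(grid_value(g, c(0, 0, min(dz, geom$pipette_length))) -
                  grid_value(g, c(0, 0, -min(dz, geom$bath_box[3]))))
    expect_gte(near / 600, 0.5)
    # force on a negative charge just inside the pipette points into the bath
    f <- grid_force(g, c(0, 0, 3), charge_or_unit = -1)
    expect_lt(f[3], 0)
  }
  g0 <- build_electrostatic_grid(geom, bias = 0)
  expect_true(all(g0$values == 0))
  expect_true(all(grid_force(g0, c(1, 2, -3), -5) == 0))
})

test_that("axial resistance profile agrees with numerical quadrature", {
  geom <- pore_geometry()
  a <- geom$aperture_diameter / 2
  tth <- tanpi(geom$cone_half_angle / 180)
  zmin <- -geom$bath_box[3]
  dens <- function(z) ifelse(z < 0, 1 / (2 * pi * (z^2 + a^2)),
                             1 / (pi * (a + z * tth)^2))
  for (z in c(-20, -5, 0, 3, 40, 120)) {
    num <- stats::integrate(dens, zmin, z, rel.tol = 1e-10)$value
    expect_equal(nanoject:::axial_resistance_profile(geom, z), num,
                 tolerance = 1e-6)
  }
})

test_that("grid_force is exact on uniform and linear grids and close to finite differences on smooth grids", {
  mk <- function(f) {
    ax <- seq(0, 10, by = 0.5)
    vals <- array(0, c(21, 21, 21))
    for (i in 1:21) for (j in 1:21) for (k in 1:21)
      vals[i, j, k] <- f(ax[i], ax[j], ax[k])
    potential_grid(c(0, 0, 0), 0.5, vals, "mobility")
  }
  gu <- mk(function(x, y, z) 7)
  expect_equal(grid_force(gu, c(3.3, 4.4, 5.5)), matrix(0, 1, 3))
  gl <- mk(function(x, y, z) 2 * x - 3 * y + 0.5 * z)
  set.seed(1)
  pts <- matrix(stats::runif(30, 2, 8), 10, 3)
  f <- grid_force(gl, pts, charge_or_unit = 2)
  expect_equal(f, matrix(rep(-2 * c(2, -3, 0.5), each = 10), 10, 3),
               tolerance = 1e-9)
  gs <- mk(function(x, y, z) sin(x / 2) + cos(y / 3) * sin(z / 4))
  pts <- matrix(stats::runif(300, 2, 8), 100, 3)
  f <- grid_force(gs, pts)
  h <- 0.5 # one voxel: a symmetric difference of the interpolated field
  for (d in 1:3) {
    pp <- pts; pp[, d] <- pp[, d] + h
    pm <- pts; pm[, d] <- pm[, d] - h
    fd <- -(grid_value(gs, pp) - grid_value(gs, pm)) / (2 * h)
    expect_lt(max(abs(f[, d] - fd)) / max(abs(fd)), 0.05)
  }
})

test_that("grid_force is translation-consistent and handles out-of-bounds per flag", {
  ax <- seq(0, 8)
  set.seed(2)
  vals <- array(stats::rnorm(9^3), c(9, 9, 9))
  g1 <- potential_grid(c(0, 0, 0), 1, vals, "mobility")
  g2 <- potential_grid(c(5, -3, 11), 1, vals, "mobility")
  p <- matrix(c(3.21, 4.56, 2.87), 1, 3)
  f1 <- grid_force(g1, p)
  f2 <- grid_force(g2, p + rep(c(5, -3, 11), each = 1))
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_warning(grid_force(g1, c(20, 1, 1)), "clamped")
  expect_error(grid_force(g1, c(20, 1, 1), out_of_bounds = "error"), "outside")
})

test_that("potential_grid validates values", {
  expect_error(potential_grid(c(0, 0, 0), 1, array(NA_real_, c(2, 2, 2)),
                              "steric_dna"), "finite")
  expect_error(potential_grid(c(0, 0, 0), 1, array(-1, c(2, 2, 2)),
                              "steric_dna"), ">= 0")
  expect_error(potential_grid(c(0, 0, 0), 0, array(1, c(2, 2, 2)),
                              "mobility"), "spacing")
})
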