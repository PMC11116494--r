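test_that("bead counts and contour lengths follow the resolution arithmetic", {
  m <- build_dna(2700, nt_per_bead = 10)
  expect_identical(m$n_beads, 540)
  expect_equal(m$contour_length, 918, tolerance = m$bond_rest_length / 918)
  m7 <- build_dna(7000, nt_per_bead = 10)
  expect_equal(m7$contour_length, 2380, tolerance = m7$bond_rest_length / 2380)
  expect_error(build_dna(5), "n_bp")
  expect_error(build_dna(100, nt_per_bead = 7), "even")
  expect_error(build_dna(10, nt_per_bead = 40), "exceeds")
})

test_that("discrete WLC stiffness reproduces the target persistence length in direct sampling", {
  m <- build_dna(600)
  set.seed(11)
  # mean deflection cosine of sampled chains matches exp(-b/Lp)
  n <- 120
  rg <- sample_wlc_rg(m, 50) # also exercises the sampler path
  expect_true(all(rg > 0))
  expect_equal(1 / tanh(m$alpha) - 1 / m$alpha,
               exp(-m$bond_rest_length / m$persistence_length),
               tolerance = 1e-10)
})

test_that("free-chain equilibrium Rg agrees with the Benoit-Doty closed form", {
  m <- build_dna(2700, nt_per_bead = 10)
  set.seed(7)
  rg <- sample_wlc_rg(m, 400)
  want <- wlc_rg_theory(m$contour_length, m$persistence_length)
  expect_equal(sqrt(mean(rg^2)), want, tolerance = 0.2)
})

test_that("bonded forces vanish on a straight relaxed chain and follow Hooke's law for a stretched bond", {
  m <- build_dna(100)
  b <- m$bond_rest_length
  straight <- cbind(0, 0, seq(0, by = b, length.out = m$n_beads))
  f <- internal_forces(straight, m)
  expect_lt(max(abs(f)), 1e-10)
  two <- build_dna(10, nt_per_bead = 4)
  delta <- 0.12
  pos <- cbind(0, 0, c(0, cumsum(rep(two$bond_rest_length, two$n_beads - 1))))
  pos[two$n_beads, 3] <- pos[two$n_beads, 3] + delta
  f2 <- internal_forces(pos, two)
  expect_equal(f2[two$n_beads, 3], -two$bond_stiffness * delta,
               tolerance = 1e-10)
})

test_that("analytic forces equal the numerical energy gradient, with zero net force and torque", {
  m <- build_dna(100) # 20 beads
  set.seed(3)
  pos <- cbind(0, 0, seq(0, by = m$bond_rest_length, length.out = m$n_beads)) +
    matrix(stats::rnorm(m$n_beads * 3, sd = 0.3), ncol = 3)
  f <- internal_forces(pos, m)
  g <- numerical_chain_gradient(pos, m)
  rel <- max(abs(f + g)) / max(abs(g))
  expect_lt(rel, 1e-4)
  expect_lt(max(abs(colSums(f))), 1e-9)
  torque <- colSums(cbind(
    pos[, 2] * f[, 3] - pos[, 3] * f[, 2],
    pos[, 3] * f[, 1] - pos[, 1] * f[, 3],
    pos[, 1] * f[, 2] - pos[, 2] * f[, 1]))
  expect_lt(max(abs(torque)), 1e-9)
  pos[1, 1] <- NaN
  expect_error(internal_forces(pos, m), "finite")
})

test_that("radius of gyration matches hand values and the brute-force double loop", {
  expect_identical(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(0, 0, 4))), 2)
  set.seed(5)
  pts <- matrix(stats::rnorm(300), 100, 3)
  expect_equal(radius_of_gyration(pts), brute_force_rg(pts), tolerance = 1e-12)
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("BD dynamics preserve the equilibrium bond-direction correlations of the built chain", {
  m <- build_dna(300)
  n <- m$n_beads
  set.seed(21)
  # start from an equilibrium bending configuration (independent direct
  # sampler) so the dynamics only have to maintain the ensemble
  sample_wlc_positions <- function(m) {
    pos <- matrix(0, m$n_beads, 3)
    u <- c(0, 0, 1)
    ea <- exp(-2 * m$alpha)
    for (i in 2:m$n_beads) {
      if (i > 2) {
        cphi <- 1 + log(stats::runif(1) * (1 - ea) + ea) / m$alpha
        sphi <- sqrt(max(0, 1 - cphi^2))
        psi <- stats::runif(1, 0, 2 * pi)
        e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
                u[1] * e1[2] - u[2] * e1[1])
        u <- cphi * u + sphi * (cos(psi) * e1 + sin(psi) * e2)
        u <- u / sqrt(sum(u^2))
      }
      pos[i, ] <- pos[i - 1, ] + m$bond_rest_length * u
    }
    pos
  }
  kT <- kT_kcal()
  dt <- 2e-3
  corr <- matrix(0, 0, 4)
  for (chain in 1:2) {
    pos <- sample_wlc_positions(m)
    for (step in 1:40000) {
      pos <- bd_step(pos, internal_forces(pos, m), m$bead_D, dt, kT)
      if (step > 4000 && step %% 200 == 0) {
        bv <- diff(pos)
        bv <- bv / sqrt(rowSums(bv^2))
        corr <- rbind(corr, vapply(1:4, function(s) {
          mean(rowSums(bv[seq_len(n - 1 - s), , drop = FALSE] *
                         bv[seq_len(n - 1 - s) + s, , drop = FALSE]))
        }, 0))
      }
    }
  }
  cs <- colMeans(corr)
  fit <- stats::lm(log(cs) ~ seq_along(cs) + 0)
  lp_hat <- -m$bond_rest_length / stats::coef(fit)[[1]]
  expect_equal(lp_hat, m$persistence_length, tolerance = 0.15)
})

test_that("polymer_state enforces chain integrity and stuffing fits the pipette", {
  m <- build_dna(300)
  geom <- pore_geometry()
  set.seed(9)
  st <- init_dna_in_pipette(m, geom, start_depth = 18.5)
  expect_s3_class(st, "nj_polymer_state")
  expect_equal(st$positions[1, 3], 18.5)
  r <- sqrt(st$positions[, 1]^2 + st$positions[, 2]^2)
  expect_true(all(r <= nanoject:::cone_radius(geom, st$positions[, 3])))
  bad <- st$positions
  bad[5, ] <- bad[5, ] + 100
  expect_error(polymer_state(bad, m), "integrity")
  expect_error(init_dna_in_pipette(build_dna(2700), geom, 18.5), "fit")
})
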