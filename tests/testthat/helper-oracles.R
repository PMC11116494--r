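# Independent reference implementations used to cross-check the package's
# compiled paths, plus small reusable fixtures.

# tiny conical geometry whose grids stay below ~20^3 voxels
tiny_geometry <- function(aperture = 8, half_angle = 15, pip_len = 6,
                          width = 16, depth = 6, spacing = 1) {
  pore_geometry(aperture_diameter = aperture, cone_half_angle = half_angle,
                pipette_length = pip_len, bath_width = width,
                bath_depth = depth, spacing = spacing,
                analysis_cylinder = c(radius = 2, height = 2))
}

# brute-force all-pairs nearest-fluid-voxel distance (nm), O(N^2)
brute_force_wall_distance <- function(grid) {
  dims <- grid$dim
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(dims[a]) - 1) *
                 grid$spacing[a])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  fluid <- grid$values == 0
  d <- numeric(nrow(pts))
  fpts <- pts[fluid, , drop = FALSE]
  for (i in which(!fluid)) {
    d2 <- (fpts[, 1] - pts[i, 1])^2 + (fpts[, 2] - pts[i, 2])^2 +
      (fpts[, 3] - pts[i, 3])^2
    d[i] <- sqrt(min(d2))
  }
  array(d, dims)
}

# direct-summation convolution of a source field with the radial ramp kernel
direct_ramp_convolution <- function(src, dims, spacing, inner, outer,
                                    oob = 0) {
  w_of_r <- function(r) ifelse(r > outer, 0,
                               ifelse(r <= inner, 1, (outer - r) / (outer - inner)))
  rad <- ceiling(outer / spacing)
  offs <- expand.grid(di = -rad:rad, dj = -rad:rad, dk = -rad:rad)
  offs$r <- sqrt(offs$di^2 + offs$dj^2 + offs$dk^2) * spacing
  offs <- offs[w_of_r(offs$r) > 0, ]
  offs$w <- w_of_r(offs$r) / sum(w_of_r(offs$r))
  src <- array(src, dims)
  out <- array(0, dims)
  for (i in seq_len(dims[1]))
    for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        ii <- i + offs$di; jj <- j + offs$dj; kk <- k + offs$dk
        inb <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] &
          kk >= 1 & kk <= dims[3]
        s <- rep(oob, nrow(offs))
        s[inb] <- src[cbind(ii[inb], jj[inb], kk[inb])]
        out[i, j, k] <- sum(offs$w * s)
      }
  out
}

# numerical gradient of the chain energy (central differences)
numerical_chain_gradient <- function(pos, model, h = 1e-5) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos)))
    for (d in 1:3) {
      pp <- pos; pp[i, d] <- pp[i, d] + h
      pm <- pos; pm[i, d] <- pm[i, d] - h
      g[i, d] <- (internal_energy(pp, model) - internal_energy(pm, model)) /
        (2 * h)
    }
  g
}

# double-loop radius of gyration
brute_force_rg <- function(pos) {
  m <- nrow(pos)
  ctr <- colMeans(pos)
  sqrt(sum((t(pos) - ctr)^2) / m)
}

# all-pairs reference forces replicating the engine's pair interaction
# (Rmin-form LJ, force capped below 0.6 Rmin, repulsive-only option),
# written independently in R
reference_pair_forces <- function(pos, n_dna, dna, crowders) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  cross <- nanoject:::crowder_cross_pars(crowders, dna)
  par_of <- function(i, j) {
    di <- i <= n_dna; dj <- j <= n_dna
    if (di && dj) list(rmin = dna$bead_rmin, eps = dna$epsilon_self,
                       cut = dna$bead_rmin, rep = TRUE)
    else if (!di && !dj) list(rmin = crowders$rmin_cc, eps = crowders$epsilon_cc,
                              cut = 3 * crowders$rmin_cc, rep = FALSE)
    else list(rmin = cross$rmin_cd, eps = cross$eps_cd,
              cut = 3 * cross$rmin_cd, rep = FALSE)
  }
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      if (i <= n_dna && j <= n_dna && j - i <= 2) next
      p <- par_of(i, j)
      dvec <- pos[j, ] - pos[i, ]
      r2 <- sum(dvec^2)
      if (r2 >= p$cut^2) next
      if (p$rep && r2 >= p$rmin^2) next
      r2e <- max(r2, 0.36 * p$rmin^2)
      s6 <- (p$rmin^2 / r2e)^3
      fr <- 12 * p$eps * (s6^2 - s6) / r2e
      f[i, ] <- f[i, ] - fr * dvec
      f[j, ] <- f[j, ] + fr * dvec
    }
  f
}

# synthetic toy trajectory: beads marching down the z axis at constant speed
toy_trajectory <- function(n_dna = 4, n_crw = 0, nf = 11, dt = 1,
                           z0 = NULL, speed = 1, bp_per_bead = 5,
                           crw_pos = NULL) {
  z0 <- z0 %||% seq(2, by = 2, length.out = n_dna)
  n <- n_dna + n_crw
  frames <- array(0, c(n, 3, nf))
  times <- (seq_len(nf) - 1) * dt
  for (t in seq_len(nf)) {
    z <- z0 - speed * times[t]
    frames[seq_len(n_dna), 3, t] <- z
    if (n_crw > 0) frames[(n_dna + 1):n, , t] <- crw_pos
  }
  crossing <- (z0 / speed)
  completed <- all(z0 - speed * max(times) < 0)
  trajectory(times = times, frames = frames, n_dna = n_dna,
             bp_per_bead = bp_per_bead,
             crossing_ns = ifelse(crossing <= max(times), crossing, NA),
             completed = completed, params = sim_params(), crowded = n_crw > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
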