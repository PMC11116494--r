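#' Conical nanopipette geometry
#'
#' Defines the simulation domain: a conical pipette whose circular aperture
#' sits at the plane z = 0 (z > 0 inside the pipette, z < 0 in the bath), a
#' rectangular bath box below the aperture, and the voxel spacing used for
#' the potential grids.
#'
#' @param aperture_diameter Aperture diameter (nm).
#' @param cone_half_angle Inner half-angle of the pipette cone (degrees).
#'   Pulled quartz/borosilicate pipettes typically have inner half-cone
#'   angles of 3-15 degrees; the default is 8.
#' @param pipette_length Length of pipette interior modelled above the
#'   aperture (nm).
#' @param bath_width Lateral extent of the bath box (nm, both x and y).
#' @param bath_depth Depth of the bath below the aperture (nm).
#' @param spacing Voxel spacing of the potential grids (nm). Must resolve the
#'   aperture with at least 4 voxels.
#' @param wall_margin Thickness of the confining wall layer at the outer
#'   domain boundary (nm).
#' @param analysis_cylinder Radius and height (nm) of the crowder-analysis
#'   cylinder below the aperture; the bath must contain it.
#' @return An object of class `nj_geometry`.
#' @export
pore_geometry <- function(aperture_diameter = 10, cone_half_angle = 8,
                          pipette_length = 130, bath_width = 52,
                          bath_depth = 32, spacing = 1, wall_margin = 1,
                          analysis_cylinder = c(radius = 15, height = 30)) {
  if (aperture_diameter <= 0) stop("aperture_diameter must be > 0")
  if (cone_half_angle <= 0 || cone_half_angle >= 90)
    stop("cone_half_angle must be in (0, 90): the cone must widen away from the aperture")
  if (spacing > aperture_diameter / 4)
    stop("configuration error: spacing too coarse to resolve the aperture ",
         "(need >= 4 voxels across ", aperture_diameter, " nm)")
  top_radius <- aperture_diameter / 2 + pipette_length * tanpi(cone_half_angle / 180)
  if (top_radius > bath_width / 2 - wall_margin)
    stop("bath_width too small to contain the pipette cone (top radius ",
         round(top_radius, 1), " nm)")
  if (bath_width / 2 - wall_margin < analysis_cylinder[["radius"]] ||
      bath_depth - wall_margin < analysis_cylinder[["height"]])
    stop("bath_box too small to contain the crowder analysis cylinder")
  structure(list(
    aperture_diameter = aperture_diameter,
    cone_half_angle = cone_half_angle,
    pipette_length = pipette_length,
    bath_box = c(bath_width, bath_width, bath_depth),
    aperture_plane_z = 0,
    spacing = spacing,
    wall_margin = wall_margin,
    analysis_cylinder = analysis_cylinder
  ), class = "nj_geometry")
}

#' @exportS3Method base::print
print.nj_geometry <- function(x, ...) {
  cat("Nanopipette geometry\n")
  cat(sprintf("  aperture: %g nm diameter at z = 0, half-angle %g deg\n",
              x$aperture_diameter, x$cone_half_angle))
  cat(sprintf("  pipette interior: z in [0, %g] nm; bath: %g x %g x %g nm below\n",
              x$pipette_length, x$bath_box[1], x$bath_box[2], x$bath_box[3]))
  invisible(x)
}

# voxel-centre axes of the full-domain grid
grid_axes <- function(geom, spacing = geom$spacing) {
  half <- geom$bath_box[1] / 2
  list(
    x = seq(-half, half, by = spacing),
    y = seq(-half, half, by = spacing),
    z = seq(-geom$bath_box[3], geom$pipette_length, by = spacing)
  )
}

# pipette cone interior radius at height z above the aperture
cone_radius <- function(geom, z) {
  geom$aperture_diameter / 2 + z * tanpi(geom$cone_half_angle / 180)
}

#' Fluid-region predicate
#'
#' TRUE where a point lies in fluid: in the bath (z < 0) or inside the
#' pipette cone (z >= 0), and away from the confining outer-boundary wall.
#'
#' @param geom An `nj_geometry`.
#' @param x,y,z Coordinates (nm), recycled to a common length.
#' @return Logical vector.
#' @export
is_fluid <- function(geom, x, y, z) {
  m <- geom$wall_margin
  half <- geom$bath_box[1] / 2
  r <- sqrt(x^2 + y^2)
  in_box <- abs(x) < half - m + 1e-9 & abs(y) < half - m + 1e-9 &
    z > -geom$bath_box[3] + m - 1e-9 & z < geom$pipette_length - m + 1e-9
  in_cone <- z >= 0 & r < cone_radius(geom, z)
  in_box & (z < 0 | in_cone)
}

#' Construct a potential grid object
#'
#' @param origin Coordinates (nm) of the first voxel centre.
#' @param spacing Voxel spacing (nm), length 1 or 3.
#' @param values 3D array of values (kcal/mol for steric grids, mV for
#'   electrostatic, dimensionless for mobility factors).
#' @param kind One of "steric_dna", "steric_crowder", "electrostatic",
#'   "mobility".
#' @return An object of class `nj_grid`.
#' @export
potential_grid <- function(origin, spacing, values, kind) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (!all(is.finite(values))) stop("grid values must all be finite")
  kind <- match.arg(kind, c("steric_dna", "steric_crowder", "electrostatic",
                            "mobility"))
  if (startsWith(kind, "steric") && any(values < -1e-12))
    stop("steric grid values must be >= 0")
  structure(list(
    origin = as.numeric(origin), spacing = spacing,
    dim = dim(values), values = as.numeric(values), kind = kind
  ), class = "nj_grid")
}

#' @exportS3Method base::print
print.nj_grid <- function(x, ...) {
  cat(sprintf("Potential grid [%s]: %d x %d x %d voxels, spacing %g nm\n",
              x$kind, x$dim[1], x$dim[2], x$dim[3], x$spacing[1]))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Harmonic steric grid for DNA beads
#'
#' Voxels in fluid get 0; voxels inside the wall get `0.5 * k * d^2` where
#' `d` is the Euclidean distance (in angstrom) to the nearest fluid voxel and
#' `k` the wall stiffness.
#'
#' @param geom An `nj_geometry`.
#' @param spacing Voxel spacing (nm); defaults to the geometry's.
#' @param k Wall stiffness in kcal/mol/A^2 (default 2).
#' @return An `nj_grid` of kind "steric_dna" (values kcal/mol).
#' @export
build_steric_grid <- function(geom, spacing = geom$spacing, k = 2) {
  if (spacing > geom$aperture_diameter / 4)
    stop("configuration error: spacing too coarse to resolve the aperture")
  ax <- grid_axes(geom, spacing)
  dims <- lengths(ax)
  fl <- fluid_mask(geom, ax)
  d2_nm2 <- edt_sq_cpp(as.logical(fl), as.integer(dims), rep(spacing, 3))
  vals <- 0.5 * k * (d2_nm2 * 100) # d^2 in A^2 = 100 * nm^2
  vals[fl] <- 0
  dim(vals) <- dims
  potential_grid(vapply(ax, `[`, 0, 1), spacing, vals, "steric_dna")
}

fluid_mask <- function(geom, ax) {
  g <- expand.grid(x = ax$x, y = ax$y, z = ax$z)
  m <- is_fluid(geom, g$x, g$y, g$z)
  dim(m) <- lengths(ax)
  m
}

#' Steric grid for crowder centres
#'
#' The wall penalty field (`penalty` kcal/mol on wall voxels and outside the
#' domain, 0 in fluid) is convolved with a normalised radial ramp kernel
#' representing the crowder size, and the DNA harmonic steric grid is added,
#' following the construction used for the BSA sphere centres.
#'
#' @inheritParams build_steric_grid
#' @param kernel_inner,kernel_outer Ramp bounds (nm, default 2.5 and 4.5).
#' @param penalty Wall penalty before convolution (kcal/mol, default 10).
#' @param ramp `"decreasing"` (default): kernel weight 1 at the centre
#'   falling linearly to 0 at `kernel_outer`; `"increasing"`: weight rising
#'   from 0 at `kernel_inner` to 1 at `kernel_outer` (the literal reading of
#'   the construction; unusual for a size kernel, see the methods vignette).
#' @param dna_grid Optional pre-built DNA steric grid to add (built if NULL).
#' @return An `nj_grid` of kind "steric_crowder".
#' @export
build_crowder_steric_grid <- function(geom, spacing = geom$spacing,
                                      kernel_inner = 2.5, kernel_outer = 4.5,
                                      penalty = 10,
                                      ramp = c("decreasing", "increasing"),
                                      dna_grid = NULL) {
  ramp <- match.arg(ramp)
  if (kernel_inner >= kernel_outer)
    stop("kernel_inner must be < kernel_outer")
  ax <- grid_axes(geom, spacing)
  dims <- lengths(ax)
  if (2 * kernel_outer >= min(diff(range(ax$x)), diff(range(ax$z))))
    stop("configuration error: kernel larger than grid")
  fl <- fluid_mask(geom, ax)
  src <- ifelse(fl, 0, penalty)
  conv <- convolve_ramp_cpp(as.numeric(src), as.integer(dims),
                            rep(spacing, 3), kernel_inner, kernel_outer,
                            ramp == "decreasing", penalty)
  if (is.null(dna_grid)) dna_grid <- build_steric_grid(geom, spacing)
  vals <- conv + dna_grid$values
  vals <- pmax(vals, 0)
  dim(vals) <- dims
  potential_grid(vapply(ax, `[`, 0, 1), spacing, vals, "steric_crowder")
}

# cumulative series resistance (units 1/(sigma)) from the bath floor up to z.
# Bath side: hemispherical access shells, dR/dz = 1/(2 pi (z^2 + a^2)).
# Pipette side: conical resistor, dR/dz = 1/(pi r(z)^2), r(z) = a + z tan(theta).
axial_resistance_profile <- function(geom, z) {
  a <- geom$aperture_diameter / 2
  t <- tanpi(geom$cone_half_angle / 180)
  zmin <- -geom$bath_box[3]
  bath_part <- (atan(pmin(z, 0) / a) - atan(zmin / a)) / (2 * pi * a)
  cone_part <- ifelse(z > 0,
                      (1 / a - 1 / (a + pmax(z, 0) * t)) / (pi * t),
                      0)
  bath_part + cone_part
}

#' Electrostatic potential grid (analytic conical-resistor model)
#'
#' The applied bias is distributed along the pore axis in proportion to the
#' cumulative series resistance of circular cross-sections: hemispherical
#' access shells on the bath side and the widening cone on the pipette side.
#' The axial profile is mapped to 3D by nearest-axial-plane assignment. The
#' pipette interior is held at `-bias` relative to the far bath so that the
#' electric force on negatively charged DNA beads points from pipette to
#' bath (the ejecting polarity).
#'
#' @inheritParams build_steric_grid
#' @param bias Magnitude of the applied bias (mV, default 600).
#' @return An `nj_grid` of kind "electrostatic" (values mV).
#' @export
build_electrostatic_grid <- function(geom, bias = 600, spacing = geom$spacing) {
  ax <- grid_axes(geom, spacing)
  dims <- lengths(ax)
  if (bias == 0) {
    vals <- array(0, dims)
  } else {
    R <- axial_resistance_profile(geom, ax$z)
    vprof <- -abs(bias) * R / R[length(R)]
    vals <- array(rep(vprof, each = dims[1] * dims[2]), dims)
  }
  g <- potential_grid(vapply(ax, `[`, 0, 1), spacing, vals, "electrostatic")
  g$bias <- bias
  g
}

#' Force from a potential grid
#'
#' Trilinear interpolation of node-centred gradients; the returned force is
#' `-charge_or_unit * grad(values)` and is continuous across voxel
#' boundaries. For steric grids use `charge_or_unit = 1` (values are energies
#' in kcal/mol); for the electrostatic grid pass the bead charge in units of
#' e (the mV-to-kcal/mol conversion is applied internally).
#'
#' @param grid An `nj_grid`.
#' @param position Numeric matrix (m x 3) or length-3 vector of positions (nm).
#' @param charge_or_unit Scalar or per-row vector multiplier.
#' @param out_of_bounds `"clamp"` (warn and clamp to the grid boundary) or
#'   `"error"`.
#' @return m x 3 matrix of forces (kcal/mol/nm).
#' @export
grid_force <- function(grid, position, charge_or_unit = 1,
                       out_of_bounds = c("clamp", "error")) {
  out_of_bounds <- match.arg(out_of_bounds)
  pos <- to_pos_matrix(position)
  lo <- grid$origin
  hi <- grid$origin + (grid$dim - 1) * grid$spacing
  bad <- pos[, 1] < lo[1] | pos[, 1] > hi[1] |
    pos[, 2] < lo[2] | pos[, 2] > hi[2] |
    pos[, 3] < lo[3] | pos[, 3] > hi[3]
  if (any(bad)) {
    if (out_of_bounds == "error") stop("position outside grid bounds")
    warning(sum(bad), " position(s) outside grid bounds; clamped")
  }
  scale <- rep(as.numeric(charge_or_unit), length.out = nrow(pos))
  if (grid$kind == "electrostatic") scale <- scale * mv_e_to_kcal()
  grid_force_cpp(unclass(grid), pos, scale)
}

#' Interpolated value of a potential grid
#'
#' @inheritParams grid_force
#' @return Numeric vector of interpolated grid values.
#' @export
grid_value <- function(grid, position) {
  grid_value_cpp(unclass(grid), to_pos_matrix(position))
}

to_pos_matrix <- function(position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3, byrow = TRUE)
  storage.mode(position) <- "double"
  position
}

#' Build the full set of grids for a geometry
#'
#' @param geom An `nj_geometry`.
#' @param bias Applied bias magnitude (mV).
#' @param steric_k Wall stiffness (kcal/mol/A^2).
#' @param ... Passed to [build_crowder_steric_grid()].
#' @return List with elements `steric_dna`, `steric_crowder`, `electrostatic`.
#' @export
build_system_grids <- function(geom, bias = 600, steric_k = 2, ...) {
  gd <- build_steric_grid(geom, k = steric_k)
  gc <- build_crowder_steric_grid(geom, dna_grid = gd, ...)
  ge <- build_electrostatic_grid(geom, bias = bias)
  list(steric_dna = gd, steric_crowder = gc, electrostatic = ge)
}
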