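## Internal unit system: nm, ns, kcal/mol, elementary charge, mV.
## All conversions derive from CODATA constants at load time; nothing is
## hard-coded downstream.

#' Thermal energy in kcal/mol
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kcal/mol (0.5783 at 291 K).
#' @export
kT_kcal <- function(temperature = 291) {
  8.314462618 * temperature / 4184
}

# kcal/mol per (elementary charge x millivolt)
mv_e_to_kcal <- function() {
  96485.33212 * 1e-3 / 4184
}

# 1 kcal/mol expressed in Da nm^2 / ns^2 (for D = kT / (m * gamma))
kcalmol_to_da_nm2_ns2 <- function() {
  4184 * 1000 # J/mol -> g/mol m^2/s^2, and m^2/s^2 == nm^2/ns^2
}

# Stokes-Einstein diffusivity (nm^2/ns) of a sphere of radius r_nm in water
stokes_einstein_D <- function(radius_nm, temperature = 291,
                              viscosity_Pa_s = 1.06e-3) {
  kB <- 1.380649e-23
  D_m2s <- kB * temperature / (6 * pi * viscosity_Pa_s * radius_nm * 1e-9)
  D_m2s * 1e9 # m^2/s -> nm^2/ns
}

# diffusivity from a damping rate gamma (1/ns) and mass (Da): D = kT/(m gamma)
damping_to_D <- function(damping_ns, mass_da, temperature = 291) {
  kT_kcal(temperature) * kcalmol_to_da_nm2_ns2() / (mass_da * damping_ns)
}

avogadro <- function() 6.02214076e23
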