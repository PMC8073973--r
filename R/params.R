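#' Kinetic and transport parameters
#'
#' Constants and fitted parameters of the hydrolysis model, in the model's
#' unit system (cm, g, mol, min):
#' \describe{
#'   \item{k_ads}{cellulase surface adsorption rate, cm3/(mol min);
#'     literature value 3e10.}
#'   \item{k_des}{cellulase surface desorption rate, 1/min; literature value
#'     0.068.}
#'   \item{sigma}{binding sites per accessible surface, mol/cm2; 2.1e-12 from
#'     the 51 Angstrom spherical footprint.}
#'   \item{M_p}{moles of glucose liberated per mole of enzyme during one
#'     adsorption-reaction-desorption cycle (lumped hydrolytic capacity,
#'     equivalent to an average intrinsic processivity); fitted, default 755.}
#'   \item{D_pore}{average cellulase pore diffusivity, cm2/min; default from
#'     Stokes-Einstein for a 51 Angstrom sphere in water at 50 C
#'     (see [stokes_einstein_diffusivity()]).}
#'   \item{tau}{pore-network tortuosity (>= 1); fitted, default 2. The
#'     time-independent diffusivity is `D_E = D_pore / tau`.}
#'   \item{H_glu}{anhydroglucose/glucose mass ratio 162/180 = 0.9 converting
#'     dissolved cellulose mass to glucose mass.}
#'   \item{MM_glu}{molar mass of glucose, 180 g/mol.}
#' }
#'
#' @param k_ads,k_des,sigma,M_p,D_pore,tau,H_glu,MM_glu see Description.
#' @return An object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(k_ads = 3e10,
                           k_des = 0.068,
                           sigma = 2.1e-12,
                           M_p = 755,
                           D_pore = stokes_einstein_diffusivity(),
                           tau = 2,
                           H_glu = 0.9,
                           MM_glu = 180) {
  p <- list(k_ads = k_ads, k_des = k_des, sigma = sigma, M_p = M_p,
            D_pore = D_pore, tau = tau, H_glu = H_glu, MM_glu = MM_glu)
  for (nm in names(p)) {
    if (length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("'", nm, "' must be a single finite number")
    # M_p = 0 is the adsorption-only limit (no catalysis), all others > 0
    if (p[[nm]] < 0 || (p[[nm]] == 0 && nm != "M_p"))
      stop("'", nm, "' must be positive")
  }
  if (tau < 1) warning("tortuosity < 1 is unphysical; proceeding anyway")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic/transport parameters\n")
  cat(sprintf("  k_ads   %g cm3/(mol min)\n", x$k_ads))
  cat(sprintf("  k_des   %g 1/min\n", x$k_des))
  cat(sprintf("  sigma   %g mol/cm2\n", x$sigma))
  cat(sprintf("  M_p     %g mol glucose / mol enzyme cycle\n", x$M_p))
  cat(sprintf("  D_pore  %g cm2/min (D_E = D_pore/tau = %g)\n",
              x$D_pore, x$D_pore / x$tau))
  cat(sprintf("  tau     %g\n", x$tau))
  cat(sprintf("  H_glu   %g, MM_glu %g g/mol\n", x$H_glu, x$MM_glu))
  invisible(x)
}

#' Update selected kinetic parameters
#'
#' @param params a [kinetic_params()] object.
#' @param ... named parameter values to replace.
#' @return A new `kinetic_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  new <- list(...)
  bad <- setdiff(names(new), names(unclass(params)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  args <- utils::modifyList(unclass(params), new)
  do.call(kinetic_params, args)
}

#' Stokes-Einstein diffusivity of a spherical enzyme
#'
#' `D = k_B T / (6 pi eta r)`, returned in cm2/min. Defaults describe a
#' lumped cellulase of 51 Angstrom diameter in water at 50 C (viscosity
#' 5.47e-4 Pa s).
#'
#' @param diameter_angstrom particle diameter in Angstrom.
#' @param temperature_K absolute temperature.
#' @param viscosity_Pa_s solvent dynamic viscosity.
#' @return Diffusivity in cm2/min.
#' @export
stokes_einstein_diffusivity <- function(diameter_angstrom = 51,
                                        temperature_K = 323.15,
                                        viscosity_Pa_s = 5.47e-4) {
  kB <- 1.380649e-23                      # J/K
  r_m <- diameter_angstrom / 2 * 1e-10    # m
  D_m2_s <- kB * temperature_K / (6 * pi * viscosity_Pa_s * r_m)
  D_m2_s * 1e4 * 60                       # cm2/min
}

#' Time-independent and effective pore diffusivity
#'
#' The effective diffusivity of enzymes in the pore network is
#' `D_eff = eps * D_pore / tau = eps * D_E`, with `D_E = D_pore / tau` its
#' time-independent part.
#'
#' @param eps porosity (0 to 1), may be a vector.
#' @param D_pore average pore diffusivity, cm2/min.
#' @param tau tortuosity (>= 1).
#' @return Effective diffusivity in cm2/min (same shape as `eps`).
#' @export
effective_diffusivity <- function(eps, D_pore, tau) {
  if (any(eps < 0 | eps > 1)) stop("porosity must lie in [0, 1]")
  if (tau < 1) warning("tortuosity < 1 is unphysical")
  eps * D_pore / tau
}

#' Operating conditions from enzyme and biomass loadings
#'
#' Converts the two key experimental parameters -- the enzyme loading `e_l`
#' (moles of enzyme per mole of initially accessible binding sites; `e_l = 1`
#' is exactly full-coverage stoichiometry) and the biomass loading `b_l`
#' (g dry substrate per cm3 bulk liquid) -- into the bulk-side bookkeeping of
#' one representative particle, per unit particle length:
#' particle mass `m_p = rho_p pi R^2`, bulk volume `V_B = m_p / b_l`, total
#' enzyme moles `n_E0 = e_l * site_density * m_p` and initial bulk enzyme
#' concentration `C_E0 = n_E0 / V_B = e_l * site_density * b_l`.
#'
#' @param e_l enzyme loading, mol enzyme / mol initial sites (>= 0).
#' @param b_l biomass loading, g/cm3 (> 0); 2 percent dry matter is about 0.02.
#' @param spec a [substrate_spec()].
#' @param derived optional [derive_substrate()] result for `spec`.
#' @return An object of class `"operating_conditions"` with fields `e_l`,
#'   `b_l`, `V_B_cm3`, `n_E0_mol`, `C_E0_mol_per_cm3`, `m_p_g` (all per unit
#'   particle length).
#' @export
operating_conditions <- function(e_l, b_l, spec, derived = NULL) {
  stopifnot(inherits(spec, "substrate_spec"))
  if (length(e_l) != 1L || e_l < 0) stop("'e_l' must be a single number >= 0")
  if (length(b_l) != 1L || b_l <= 0) stop("'b_l' must be a single number > 0")
  if (is.null(derived)) derived <- derive_substrate(spec)
  m_p <- spec$apparent_density_g_cm3 * pi * spec$radius_cm^2
  V_B <- m_p / b_l
  pore_vol <- derived$eps0 * pi * spec$radius_cm^2
  if (V_B <= pore_vol)
    stop("infeasible loading: bulk volume (", format(V_B, digits = 4),
         " cm3) does not exceed the particle pore volume (",
         format(pore_vol, digits = 4), " cm3); lower b_l")
  n_E0 <- e_l * derived$site_density_mol_per_g * m_p
  structure(
    list(
      e_l = e_l, b_l = b_l,
      m_p_g = m_p,
      V_B_cm3 = V_B,
      n_E0_mol = n_E0,
      C_E0_mol_per_cm3 = n_E0 / V_B
    ),
    class = "operating_conditions"
  )
}

#' @export
print.operating_conditions <- function(x, ...) {
  cat("Operating conditions (per unit particle length)\n")
  cat(sprintf("  e_l    %g mol enzyme / mol initial sites\n", x$e_l))
  cat(sprintf("  b_l    %g g/cm3\n", x$b_l))
  cat(sprintf("  V_B    %g cm3, particle mass %g g\n", x$V_B_cm3, x$m_p_g))
  cat(sprintf("  n_E0   %g mol, C_E0 %g mol/cm3\n",
              x$n_E0_mol, x$C_E0_mol_per_cm3))
  invisible(x)
}

#' Convert a mass-based enzyme loading to a molar site ratio
#'
#' Experimental loadings are often reported as mg protein per g dry
#' substrate. Dividing by the (assumed) enzyme molar mass gives moles of
#' enzyme per g substrate; dividing by the substrate's binding-site density
#' gives the molar site ratio `e_l` the model uses.
#'
#' @param mg_per_g enzyme loading in mg protein / g dry substrate.
#' @param site_density_mol_per_g binding sites per g substrate
#'   (`derive_substrate(spec)$site_density_mol_per_g`).
#' @param enzyme_molar_mass_g_mol lumped cellulase molar mass; the default
#'   65000 g/mol is an assumption, adjust to the cocktail at hand.
#' @return The molar enzyme loading `e_l`.
#' @export
el_from_mass_loading <- function(mg_per_g, site_density_mol_per_g,
                                 enzyme_molar_mass_g_mol = 65000) {
  if (any(mg_per_g < 0)) stop("'mg_per_g' must be >= 0")
  if (any(site_density_mol_per_g <= 0))
    stop("'site_density_mol_per_g' must be positive")
  (mg_per_g / 1000) / enzyme_molar_mass_g_mol / site_density_mol_per_g
}
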