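# Independent oracles kept deliberately separate from the package internals:
# a zero-dimensional well-mixed model, the closed-form Langmuir equilibrium,
# and a flux-integral recomputation of the glucose yield.

# Well-mixed (zero-dimensional) three-ODE model: one pore-fluid/bulk
# concentration C shared by instantaneous mixing, one bound concentration,
# one porosity. Solved directly with deSolve on its own right-hand side.
well_mixed_yield <- function(spec, derived, cond, params, times) {
  Vp <- pi * spec$radius_cm^2        # particle volume per unit length
  rhs <- function(t, y, p) {
    C <- y[1]; cs <- y[2]; eps <- y[3]
    span <- derived$eps_f - derived$eps0
    cmax <- derived$cs_max0_mol_per_cm3 *
      min(max((derived$eps_f - eps) / span, 0), 1)
    dcs <- params$k_ads * C * (cmax - cs) - params$k_des * cs
    deps <- if (eps >= derived$eps_f) 0 else
      params$k_des * cs * params$M_p * params$MM_glu * params$H_glu /
        spec$cellulose_density_g_cm3
    # free moles live in V_B + eps * Vp; adsorption sink is per total volume
    dC <- (-Vp * dcs - C * Vp * deps) / (cond$V_B_cm3 + eps * Vp)
    list(c(dC, dcs, deps))
  }
  C0 <- cond$C_E0_mol_per_cm3 * cond$V_B_cm3 /
    (cond$V_B_cm3 + derived$eps0 * Vp)   # bulk enzyme spread over all fluid
  sol <- deSolve::ode(c(C0, 0, derived$eps0), times, rhs, NULL,
                      method = "vode", rtol = 1e-10, atol = 1e-16)
  (sol[, 4] - derived$eps0) * spec$cellulose_density_g_cm3 /
    (spec$cellulose_fraction * spec$apparent_density_g_cm3)
}

# Closed-form Langmuir equilibrium coverage at free concentration C.
langmuir_theta <- function(C, k_ads, k_des) {
  K <- k_ads / k_des
  K * C / (1 + K * C)
}

# Recompute the glucose yield by integrating the desorption flux
# sum_shells k_des * C_S * M_p dV over time (trapezoidal rule on the output
# grid), converted to a fraction of total cellulose. Independent of the
# porosity bookkeeping the package uses.
flux_integral_yield <- function(sim) {
  b <- lignosim:::state_blocks(sim)
  p <- sim$params
  flux <- as.numeric(b$cs %*% sim$grid$dV) * p$k_des * p$M_p  # mol glu/min
  # the erosion cap: no glucose once local cellulose is exhausted
  capped <- b$cs
  capped[b$eps >= sim$derived$eps_f] <- 0
  flux <- as.numeric(capped %*% sim$grid$dV) * p$k_des * p$M_p
  t <- sim$times
  cum <- cumsum(c(0, diff(t) * (flux[-1] + flux[-length(flux)]) / 2))
  glucose_mass <- cum * p$MM_glu            # g glucose per unit length
  cellulose_mass <- glucose_mass * p$H_glu  # g cellulose dissolved
  cellulose_mass / (sim$spec$cellulose_fraction *
                      sim$spec$apparent_density_g_cm3 *
                      pi * sim$spec$radius_cm^2)
}

# Total enzyme moles inside the particle (pore fluid + bound), per unit
# length -- used for mole-balance complements.
particle_enzyme_moles <- function(sim) {
  b <- lignosim:::state_blocks(sim)
  as.numeric((b$eps * b$cf) %*% sim$grid$dV) +
    as.numeric(b$cs %*% sim$grid$dV)
}
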