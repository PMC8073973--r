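#' Uniform radial grid for the Method of Lines
#'
#' Vertex-centered uniform grid on \[0, R\] with `n` interior nodes at
#' `r_i = (i - 1/2) dr`, staggered away from the r = 0 singularity; the bulk
#' solution is node `n + 1`. Shell volumes (per unit particle length)
#' `2 pi r_i dr` sum exactly to `pi R^2`.
#'
#' @param R particle radius, cm.
#' @param n number of interior nodes (>= 10).
#' @return An object of class `"radial_grid"` with fields `n`, `R`, `dr`,
#'   `r` (node radii), `dV` (shell volumes per unit length).
#' @export
radial_grid <- function(R, n = 50) {
  if (length(R) != 1L || !is.finite(R) || R <= 0) stop("'R' must be positive")
  n <- as.integer(n)
  if (is.na(n) || n < 10L) stop("'n' must be an integer >= 10")
  dr <- R / n
  r <- (seq_len(n) - 0.5) * dr
  structure(
    list(n = n, R = R, dr = dr, r = r, dV = 2 * pi * r * dr),
    class = "radial_grid"
  )
}

#' Bound-enzyme site capacity at a given porosity
#'
#' The accessible binding-site capacity per total particle volume declines
#' linearly from its initial value to zero as porosity grows from `eps0` to
#' `eps_f` (cellulose consumed in proportion to created void):
#' `C_S,max(eps) = C_S,max(0) * (eps_f - eps) / (eps_f - eps0)`, clamped to
#' \[0, C_S,max(0)\] against transient integrator overshoot.
#'
#' @param eps porosity, scalar or vector.
#' @param derived a [derive_substrate()] result.
#' @return Site capacity in mol per cm3 total particle volume.
#' @export
site_capacity <- function(eps, derived) {
  stopifnot(inherits(derived, "substrate_derived"))
  span <- derived$eps_f - derived$eps0
  if (span <= 0) return(rep(0, length(eps)))
  frac <- (derived$eps_f - eps) / span
  derived$cs_max0_mol_per_cm3 * pmin(pmax(frac, 0), 1)
}

#' Langmuir adsorption-desorption rate
#'
#' Time derivative of the bound-enzyme concentration under the time-dependent
#' Langmuir isotherm:
#' `dC_S/dt = k_ads * C_F * (C_max - C_S) - k_des * C_S`. When capacity has
#' eroded below the current bound concentration the first term turns
#' negative (net forced desorption), which is the intended behavior.
#'
#' @param C_F free enzyme concentration in the pore fluid, mol/cm3.
#' @param C_S bound enzyme concentration per total volume, mol/cm3.
#' @param C_max current site capacity per total volume, mol/cm3.
#' @param k_ads,k_des Langmuir rate constants.
#' @return `dC_S/dt` in mol/(cm3 min).
#' @export
langmuir_rate <- function(C_F, C_S, C_max, k_ads, k_des) {
  k_ads * C_F * (C_max - C_S) - k_des * C_S
}

#' Porosity growth rate from enzyme desorption
#'
#' Each desorption event carries `M_p` glucose units into solution, so pore
#' void is created at
#' `deps/dt = k_des * C_S * M_p * MM_glu * H_glu / rho_C_IV`, forced to zero
#' once the hydrolyzable cellulose is exhausted (`eps >= eps_f`).
#'
#' @param C_S bound enzyme concentration, mol/cm3 total volume.
#' @param params a [kinetic_params()] object.
#' @param rho_C_IV cellulose density including voids, g/cm3.
#' @param eps current porosity (for the exhaustion cap); `NULL` skips the cap.
#' @param eps_f exhaustion porosity.
#' @return `deps/dt` in 1/min.
#' @export
porosity_rate <- function(C_S, params, rho_C_IV, eps = NULL, eps_f = Inf) {
  rate <- params$k_des * C_S * params$M_p * params$MM_glu * params$H_glu / rho_C_IV
  if (!is.null(eps)) rate[eps >= eps_f] <- 0
  rate
}

# ---------------------------------------------------------------------------
# Right-hand side of the 3(n+1) Method-of-Lines ODE system.
#
# State layout: y = [C_F(1..n), C_F_bulk, C_S(1..n), C_S_bulk, eps(1..n),
# eps_bulk]. The bulk slots of the C_S and eps blocks are inert (derivative
# 0, eps_bulk = 1) so that the state length is exactly 3(n+1).
#
# The free-enzyme balance is solved in conservative (finite-volume) form,
#   d(eps C_F)/dt = div(eps D_E grad C_F) - dC_S/dt,
# i.e. dC_F/dt = [div - dC_S/dt - C_F deps/dt] / eps,
# whose expansion reproduces the cylindrical diffusion term
# D_E [C'' + C'/r + (eps'/eps) C'] and the dilution term -(C_F/eps) deps/dt;
# the 1/eps on the adsorption sink is required for exact mole balance given
# that C_S is per total volume while C_F is per pore-fluid volume. Interior
# face porosities are arithmetic means; the outer face uses the bulk-node
# porosity (1) on both sides of the face, and the surface gradient is the
# one-sided second-order difference through C_bulk(R), C_n(R - dr/2),
# C_{n-1}(R - 3dr/2). With the same face flux driving both the outermost
# shell and the bulk ODE, total enzyme moles are conserved exactly up to
# integrator tolerance.
# ---------------------------------------------------------------------------

# Build the model context used by the RHS and by observables.
make_model <- function(spec, derived, params, conditions, grid) {
  list(
    spec = spec, derived = derived, params = params,
    conditions = conditions, grid = grid,
    D_E = params$D_pore / params$tau,
    S_cyl = 2 * pi * grid$R
  )
}

# RHS in deSolve signature. `state` has length 3(n+1).
hydrolysis_rhs <- function(t, state, model) {
  n <- model$grid$n
  nb <- n + 1L
  cf <- state[seq_len(nb)]
  cs <- state[nb + seq_len(nb)]
  eps <- state[2L * nb + seq_len(nb)]

  d <- model$derived
  p <- model$params
  eps_int <- eps[seq_len(n)]
  # clamp against transient overshoot for rate evaluation (state untouched)
  eps_cl <- pmin(pmax(eps_int, d$eps0), d$eps_f)

  cmax <- site_capacity(eps_cl, d)
  dcs_int <- langmuir_rate(cf[seq_len(n)], cs[seq_len(n)], cmax,
                           p$k_ads, p$k_des)
  deps_int <- porosity_rate(cs[seq_len(n)], p, model$spec$cellulose_density_g_cm3,
                            eps = eps_int, eps_f = d$eps_f)

  # diffusive fluxes (outward positive) at faces 1..n; face i at r = i dr
  dr <- model$grid$dr
  D_E <- model$D_E
  q <- numeric(n)
  if (n > 1L) {
    i <- seq_len(n - 1L)
    eps_face <- 0.5 * (eps_cl[i] + eps_cl[i + 1L])
    q[i] <- -eps_face * D_E * (cf[i + 1L] - cf[i]) / dr
  }
  # outer face at r = R: one-sided second-order gradient through the bulk
  # node value at R and the two outermost interior nodes; bulk-node porosity
  grad_R <- (8 * cf[nb] - 9 * cf[n] + cf[n - 1L]) / (3 * dr)
  q[n] <- -1 * D_E * grad_R

  A <- 2 * pi * (seq_len(n) * dr)   # face areas per unit length
  influx <- numeric(n)              # net molar influx per shell volume
  influx[1L] <- -A[1L] * q[1L] / model$grid$dV[1L]
  if (n > 1L) {
    i <- 2:n
    influx[i] <- -(A[i] * q[i] - A[i - 1L] * q[i - 1L]) / model$grid$dV[i]
  }

  eps_div <- pmax(eps_int, 1e-12)
  dcf_int <- (influx - dcs_int - cf[seq_len(n)] * deps_int) / eps_div
  # a fully closed matrix transports nothing
  closed <- eps_int < 1e-12
  if (any(closed)) dcf_int[closed] <- 0

  # bulk node: loses exactly what flows through the outer face
  dcf_bulk <- model$S_cyl * q[n] / model$conditions$V_B_cm3

  list(c(dcf_int, dcf_bulk, dcs_int, 0, deps_int, 0))
}

#' Initial state of the radial system
#'
#' All enzymes start in the bulk solution: interior nodes carry no free or
#' bound enzyme and sit at the initial porosity; the bulk node holds
#' `C_E0 = n_E0 / V_B` with porosity 1.
#'
#' @param derived a [derive_substrate()] result.
#' @param conditions an [operating_conditions()] object.
#' @param grid a [radial_grid()].
#' @return Named numeric state vector of length `3 (n + 1)`.
#' @export
initial_state <- function(derived, conditions, grid) {
  n <- grid$n
  y <- c(rep(0, n), conditions$C_E0_mol_per_cm3,   # C_F block + bulk
         rep(0, n + 1L),                           # C_S block (+ inert bulk)
         rep(derived$eps0, n), 1)                  # eps block + bulk
  names(y) <- c(paste0("cf", seq_len(n)), "cf_bulk",
                paste0("cs", seq_len(n)), "cs_bulk",
                paste0("eps", seq_len(n)), "eps_bulk")
  y
}
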