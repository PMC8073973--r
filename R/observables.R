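#' Glucose yield over time
#'
#' Cellulose dissolved per unit particle length is read off the porosity
#' field, `sum_shells (eps - eps0) rho_C_IV dV`; the yield is that mass over
#' the total cellulose initially present (`f_cell rho_p pi R^2`), so the
#' curve saturates at the digestibility `d`. Yield on the hydrolyzable-
#' cellulose basis is `yield / d`.
#'
#' @param sim a [simulate_hydrolysis()] result.
#' @param basis `"total"` (default) or `"hydrolyzable"` cellulose.
#' @return Numeric vector of yields (fractions) at the output times.
#' @export
glucose_yield <- function(sim, basis = c("total", "hydrolyzable")) {
  stopifnot(inherits(sim, "hydrolysis_sim"))
  basis <- match.arg(basis)
  b <- state_blocks(sim)
  rho_C <- sim$spec$cellulose_density_g_cm3
  dissolved <- as.numeric((b$eps - sim$derived$eps0) %*% sim$grid$dV) * rho_C
  total_cellulose <- sim$spec$cellulose_fraction *
    sim$spec$apparent_density_g_cm3 * pi * sim$spec$radius_cm^2
  if (total_cellulose <= 0) return(rep(0, length(sim$times)))
  y <- dissolved / total_cellulose
  if (basis == "hydrolyzable") {
    d <- sim$spec$digestibility
    y <- if (d > 0) y / d else rep(0, length(y))
  }
  pmax(y, 0)
}

#' Glucose titer over time
#'
#' Dissolved cellulose mass converted to glucose through the hydrolysis
#' factor (`glucose = cellulose / H_glu`), divided by the bulk volume of the
#' representative particle; reported in g/L.
#'
#' @param sim a [simulate_hydrolysis()] result.
#' @return Numeric vector, g glucose per liter of bulk liquid.
#' @export
glucose_titer <- function(sim) {
  stopifnot(inherits(sim, "hydrolysis_sim"))
  b <- state_blocks(sim)
  rho_C <- sim$spec$cellulose_density_g_cm3
  dissolved <- as.numeric((b$eps - sim$derived$eps0) %*% sim$grid$dV) * rho_C
  glucose_g <- pmax(dissolved, 0) / sim$params$H_glu
  1000 * glucose_g / sim$conditions$V_B_cm3
}

#' Cellulose surface coverage
#'
#' Fractional occupancy of the binding sites, `theta = C_S / C_S,max(eps)`
#' per node (0 where the capacity has eroded to zero), and its site-weighted
#' mean over shells. Near exhaustion the bound concentration can transiently
#' exceed the eroding capacity (adsorbed enzymes outlive the sites they sit
#' on; the isotherm then drives net desorption), so the reported coverage is
#' capped at 1; the uncapped ratio is returned as `theta_raw`.
#'
#' @param sim a [simulate_hydrolysis()] result.
#' @return A list with `theta` (times x nodes matrix, capped at 1),
#'   `theta_raw` (uncapped) and `mean` (site-weighted mean of the capped
#'   coverage over output times).
#' @export
surface_coverage <- function(sim) {
  stopifnot(inherits(sim, "hydrolysis_sim"))
  b <- state_blocks(sim)
  cmax <- matrix(site_capacity(as.numeric(b$eps), sim$derived),
                 nrow = nrow(b$eps))
  theta_raw <- ifelse(cmax > 0, b$cs / cmax, 0)
  theta <- pmin(theta_raw, 1)
  wsum <- as.numeric(cmax %*% sim$grid$dV)
  msum <- as.numeric((theta * cmax) %*% sim$grid$dV)
  list(theta = theta, theta_raw = theta_raw,
       mean = ifelse(wsum > 0, msum / wsum, 0))
}

#' Bulk enzyme depletion
#'
#' Fraction of the initial bulk enzyme concentration remaining over time
#' (reported as 1 throughout when no enzyme was loaded).
#'
#' @param sim a [simulate_hydrolysis()] result.
#' @return Numeric vector starting at 1.
#' @export
bulk_depletion <- function(sim) {
  stopifnot(inherits(sim, "hydrolysis_sim"))
  b <- state_blocks(sim)
  C0 <- sim$conditions$C_E0_mol_per_cm3
  if (C0 <= 0) return(rep(1, length(sim$times)))
  b$cf_bulk / C0
}

#' Observables table of a simulation
#'
#' @param x a [simulate_hydrolysis()] result.
#' @param row.names,optional,... ignored (S3 signature).
#' @return The results data.frame: `time_min`, `yield_fraction`,
#'   `titer_g_per_L`, `mean_coverage`, `bulk_fraction`.
#' @export
as.data.frame.hydrolysis_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  x$results
}

#' Write the observables table as CSV
#'
#' @param sim a [simulate_hydrolysis()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(sim, path) {
  utils::write.csv(sim$results, path, row.names = FALSE)
  invisible(path)
}
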