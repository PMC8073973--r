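#' Residuals of the forward model against a yield dataset
#'
#' Runs the simulator for every record of a yield dataset at candidate
#' values of the two free parameters and returns `predicted - measured`
#' yields, one residual per record. Simulation failures propagate as errors
#' (they are not converted into penalty values).
#'
#' @param M_p candidate hydrolytic capacity (> 0).
#' @param tau candidate tortuosity (>= 1).
#' @param data yield dataset: data.frame with `substrate_id`, `e_l`, `b_l`,
#'   `time_min`, `yield_fraction` (see [read_yield_csv()]).
#' @param substrates named list of [substrate_spec()] objects.
#' @param params baseline [kinetic_params()]; `M_p` and `tau` are overridden.
#' @param n,control forwarded to [simulate_hydrolysis()].
#' @return Numeric vector of residuals (predicted minus measured).
#' @export
yield_residuals <- function(M_p, tau, data, substrates,
                            params = kinetic_params(),
                            n = 50, control = solver_control()) {
  if (length(M_p) != 1L || !is.finite(M_p) || M_p <= 0)
    stop("infeasible candidate: M_p must be a single positive number")
  if (length(tau) != 1L || !is.finite(tau) || tau < 1)
    stop("infeasible candidate: tau must be a single number >= 1")
  p <- update_params(params, M_p = M_p, tau = tau)
  predict_yields(data, substrates, p, n = n, control = control) -
    data$yield_fraction
}

# Deterministic multi-start grid over log(M_p) x tau, spread to cover the
# bounded box without relying on a seed.
fit_starts <- function(lower, upper, nstart) {
  mp <- exp(seq(log(max(lower[1], 20)), log(min(upper[1], 3000)),
                length.out = nstart))
  tau <- seq(max(lower[2], 1.2), min(upper[2], 8), length.out = nstart)
  # fixed permutation so extreme M_p starts meet both low and high tau
  perm <- ((seq_len(nstart) * 2L) %% nstart) + 1L
  cbind(M_p = mp, tau = tau[perm])
}

#' Fit the hydrolytic capacity and tortuosity to yield data
#'
#' Combined bounded least-squares fit of the model's two free parameters --
#' the lumped hydrolytic capacity `M_p` (glucose released per enzyme binding
#' cycle) and the pore-network tortuosity `tau` -- over a whole dataset of
#' measured glucose yields spanning one or several substrates.
#' Levenberg-Marquardt minimization runs in `(log M_p, tau)` from a
#' deterministic grid of starting points to guard against local minima; the
#' best converged start is reported along with all starts.
#'
#' @param data yield dataset (see [yield_residuals()]); an optional
#'   `yield_se` column enables inverse-variance weighting.
#' @param substrates named list of [substrate_spec()] objects.
#' @param params baseline [kinetic_params()] for everything except `M_p`,
#'   `tau`.
#' @param lower,upper bounds `c(M_p, tau)`; defaults `c(1, 1)` and
#'   `c(5000, 10)`.
#' @param nstart number of deterministic multi-starts (>= 1, default 5).
#' @param weighted if `TRUE` and `yield_se` is present and positive, weight
#'   residuals by `1 / yield_se`; default unweighted.
#' @param n,control forwarded to [simulate_hydrolysis()].
#' @return An object of class `"hydrolysis_fit"` with components
#'   `coefficients` (named `M_p`, `tau`), `sse`, `starts` (per-start
#'   diagnostics), `fitted.values`, `residuals` (predicted - measured),
#'   `data`, and the call ingredients. Supports [coef()], [print()],
#'   [summary()], [predict()] and [residuals()].
#' @examples
#' \donttest{
#' subs <- list(mild = synthetic_substrate("mild"),
#'              severe = synthetic_substrate("severe"))
#' design <- expand.grid(substrate_id = names(subs), e_l = c(0.5, 1),
#'                       b_l = 0.02, time_min = c(30, 120),
#'                       stringsAsFactors = FALSE)
#' dat <- synthetic_yield_data(design, subs, kinetic_params(M_p = 500),
#'                             n = 14)
#' fit <- fit_hydrolysis(dat, subs, n = 14, nstart = 2)
#' coef(fit)
#' }
#' @export
fit_hydrolysis <- function(data, substrates,
                           params = kinetic_params(),
                           lower = c(1, 1), upper = c(5000, 10),
                           nstart = 5, weighted = FALSE,
                           n = 50, control = solver_control()) {
  if (nrow(data) < 2L)
    stop("need at least two yield records to fit two parameters")
  if (length(unique(data$substrate_id)) < 2L)
    message("note: fitting across a single substrate; spanning several ",
            "substrates better constrains M_p and tau jointly")
  w <- rep(1, nrow(data))
  if (isTRUE(weighted)) {
    if (is.null(data$yield_se) || any(data$yield_se <= 0))
      stop("weighted fit requires a positive 'yield_se' column")
    w <- 1 / data$yield_se
  }

  resid_fn <- function(par) {
    w * yield_residuals(exp(par[1]), par[2], data, substrates,
                        params = params, n = n, control = control)
  }

  starts <- fit_starts(lower, upper, max(1L, as.integer(nstart)))
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log(starts[i, "M_p"]), starts[i, "tau"]),
        lower = c(log(lower[1]), lower[2]),
        upper = c(log(upper[1]), upper[2]),
        fn = resid_fn,
        # epsfcn >= the solver tolerance so finite-difference Jacobian steps
        # stand clear of the ODE integration noise
        control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                             ptol = 1e-10,
                                             epsfcn = max(control$rtol, 1e-10))
      ),
      error = function(e) e
    )
  }

  ok <- vapply(runs, function(r) inherits(r, "nls.lm") && r$info %in% 1:4,
               logical(1))
  starts_tbl <- data.frame(
    start_M_p = starts[, "M_p"], start_tau = starts[, "tau"],
    M_p = vapply(runs, function(r) if (inherits(r, "nls.lm")) exp(r$par[1]) else NA_real_, 0),
    tau = vapply(runs, function(r) if (inherits(r, "nls.lm")) r$par[2] else NA_real_, 0),
    sse = vapply(runs, function(r) if (inherits(r, "nls.lm")) r$deviance else NA_real_, 0),
    info = vapply(runs, function(r) if (inherits(r, "nls.lm")) r$info else NA_integer_, 0L),
    message = vapply(runs, function(r)
      if (inherits(r, "nls.lm")) r$message else conditionMessage(r), ""),
    converged = ok
  )
  if (!any(ok)) {
    stop("no optimizer start converged; diagnostics:\n",
         paste(utils::capture.output(print(starts_tbl)), collapse = "\n"))
  }
  best <- runs[[which(ok)[which.min(starts_tbl$sse[ok])]]]
  est <- c(M_p = unname(exp(best$par[1])), tau = unname(best$par[2]))

  res <- yield_residuals(est["M_p"], est["tau"], data, substrates,
                         params = params, n = n, control = control)
  structure(
    list(
      coefficients = est,
      sse = sum((w * res)^2),
      residuals = res,
      fitted.values = data$yield_fraction + res,
      weights = w,
      starts = starts_tbl,
      data = data,
      substrates = substrates,
      params = params,
      n = n, control = control,
      lower = lower, upper = upper
    ),
    class = "hydrolysis_fit"
  )
}

#' @export
coef.hydrolysis_fit <- function(object, ...) object$coefficients

#' @export
residuals.hydrolysis_fit <- function(object, ...) object$residuals

#' @export
fitted.hydrolysis_fit <- function(object, ...) object$fitted.values

#' @export
print.hydrolysis_fit <- function(x, ...) {
  cat("Combined least-squares fit of (M_p, tau)\n")
  cat(sprintf("  M_p = %.4g glucose/cycle, tau = %.4g\n",
              x$coefficients["M_p"], x$coefficients["tau"]))
  cat(sprintf("  SSE = %.4g over %d records (%d substrates), %d/%d starts converged\n",
              x$sse, nrow(x$data), length(unique(x$data$substrate_id)),
              sum(x$starts$converged), nrow(x$starts)))
  invisible(x)
}

#' @export
summary.hydrolysis_fit <- function(object, ...) {
  per_sub <- split(object$residuals, object$data$substrate_id)
  out <- list(
    coefficients = object$coefficients,
    sse = object$sse,
    rmse = sqrt(mean(object$residuals^2)),
    n_records = nrow(object$data),
    per_substrate_rmse = vapply(per_sub, function(r) sqrt(mean(r^2)), 0),
    starts = object$starts
  )
  class(out) <- "summary.hydrolysis_fit"
  out
}

#' @export
print.summary.hydrolysis_fit <- function(x, ...) {
  cat("Combined least-squares fit of (M_p, tau)\n")
  cat(sprintf("  M_p = %.4g, tau = %.4g; SSE = %.4g, RMSE = %.4g (%d records)\n",
              x$coefficients["M_p"], x$coefficients["tau"], x$sse, x$rmse,
              x$n_records))
  cat("  per-substrate RMSE:\n")
  print(round(x$per_substrate_rmse, 5))
  cat("  multi-start diagnostics:\n")
  print(x$starts[, c("start_M_p", "start_tau", "M_p", "tau", "sse", "converged")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Predict yields from a fitted model
#'
#' @param object a [fit_hydrolysis()] result.
#' @param newdata optional design table (`substrate_id`, `e_l`, `b_l`,
#'   `time_min`); defaults to the fitting data.
#' @param substrates optional substrate list for new ids.
#' @param ... ignored.
#' @return Numeric vector of predicted yield fractions.
#' @export
predict.hydrolysis_fit <- function(object, newdata = NULL, substrates = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(substrates)) substrates <- object$substrates
  p <- update_params(object$params,
                     M_p = unname(object$coefficients["M_p"]),
                     tau = unname(object$coefficients["tau"]))
  predict_yields(newdata, substrates, p, n = object$n, control = object$control)
}

#' Plot observed versus fitted yields
#'
#' @param x a [fit_hydrolysis()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hydrolysis_fit <- function(x, ...) {
  obs <- x$data$yield_fraction
  fit <- x$fitted.values
  lim <- range(0, obs, fit)
  graphics::plot(obs, fit, xlim = lim, ylim = lim,
                 xlab = "measured yield", ylab = "predicted yield",
                 pch = as.integer(factor(x$data$substrate_id)), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = levels(factor(x$data$substrate_id)),
                   pch = seq_along(unique(x$data$substrate_id)), bty = "n")
  invisible(x)
}

#' Write a fit report as JSON
#'
#' Records the fitted parameters, SSE, all multi-start diagnostics and the
#' per-record predictions.
#'
#' @param fit a [fit_hydrolysis()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "hydrolysis_fit"))
  report <- list(
    M_p = unname(fit$coefficients["M_p"]),
    tau = unname(fit$coefficients["tau"]),
    sse = fit$sse,
    bounds = list(lower = fit$lower, upper = fit$upper),
    starts = fit$starts,
    predictions = cbind(fit$data,
                        predicted = fit$fitted.values,
                        residual = fit$residuals)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
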