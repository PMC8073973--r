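# Calibration of (M_p, tau) by combined least squares.

fit_ctl <- function() solver_control(rtol = 1e-6)

fit_fixture <- function() {
  subs <- list(mild = synthetic_substrate("mild"),
               severe = synthetic_substrate("severe"))
  design <- expand.grid(substrate_id = names(subs), e_l = c(0.5, 1),
                        b_l = 0.02, time_min = c(30, 120),
                        stringsAsFactors = FALSE)
  data <- synthetic_yield_data(design, subs, kinetic_params(M_p = 500, tau = 2),
                               n = 14, control = fit_ctl())
  list(subs = subs, data = data)
}

test_that("residuals vanish on self-generated data and match a per-record loop", {
  fx <- fit_fixture()
  r <- yield_residuals(500, 2, fx$data, fx$subs, n = 14, control = fit_ctl())
  expect_equal(max(abs(r)), 0, tolerance = 1e-12)
  # brute-force recomputation record by record (no scenario grouping)
  r2 <- yield_residuals(800, 3, fx$data, fx$subs, n = 14, control = fit_ctl())
  loop <- vapply(seq_len(nrow(fx$data)), function(i) {
    row <- fx$data[i, ]
    sim <- simulate_hydrolysis(fx$subs[[row$substrate_id]], e_l = row$e_l,
                               b_l = row$b_l, params = kinetic_params(M_p = 800, tau = 3),
                               times = c(0, row$time_min), n = 14,
                               control = fit_ctl())
    sim$results$yield_fraction[2] - row$yield_fraction
  }, 0)
  expect_equal(r2, loop, tolerance = 1e-4)
  expect_equal(sqrt(sum(r2^2)), sqrt(sum(loop^2)), tolerance = 1e-4)
})

test_that("raising the hydrolytic capacity raises reaction-limited yields", {
  fx <- fit_fixture()
  r_hi <- yield_residuals(650, 2, fx$data, fx$subs, n = 14, control = fit_ctl())
  r_lo <- yield_residuals(350, 2, fx$data, fx$subs, n = 14, control = fit_ctl())
  expect_true(all(r_hi > 0))
  expect_true(all(r_lo < 0))
})

test_that("infeasible candidates are rejected before simulation", {
  fx <- fit_fixture()
  expect_error(yield_residuals(-5, 2, fx$data, fx$subs), "M_p")
  expect_error(yield_residuals(500, 0.5, fx$data, fx$subs), "tau")
})

test_that("the fit recovers generating parameters from noise-free data", {
  fx <- fit_fixture()
  fit <- fit_hydrolysis(fx$data, fx$subs, n = 14, control = fit_ctl(),
                        nstart = 2)
  est <- coef(fit)
  expect_lt(abs(est["M_p"] - 500) / 500, 0.02)
  expect_lt(abs(est["tau"] - 2) / 2, 0.02)
  expect_s3_class(fit, "hydrolysis_fit")
  expect_true(any(fit$starts$converged))
  # fitted + residual reconstruct the data; predict() agrees on the same design
  expect_equal(fit$fitted.values - fit$residuals, fx$data$yield_fraction)
  expect_equal(unname(predict(fit, newdata = fx$data[1:2, ])),
               fit$fitted.values[1:2], tolerance = 1e-8)
})

test_that("inverse-variance weighting requires and uses standard errors", {
  fx <- fit_fixture()
  expect_error(fit_hydrolysis(fx$data, fx$subs, weighted = TRUE, n = 14,
                              control = fit_ctl()), "yield_se")
  fx$data$yield_se <- 0.02
  expect_no_error(
    fit_hydrolysis(fx$data[c(1, 4, 6), ], fx$subs, weighted = TRUE, n = 14,
                   control = fit_ctl(), nstart = 1)
  )
})

test_that("sensitivity structure separates reaction- and diffusion-limited regimes", {
  y30 <- function(spec, el, p, t = 30)
    simulate_hydrolysis(spec, e_l = el, b_l = 0.02, n = 16,
                        times = c(0, t), params = p)$results$yield_fraction[2]
  small <- ref_substrate()                   # 25 um: reaction-limited
  large <- ref_substrate(); large$radius_cm <- 0.1  # diffusion-limited
  sens <- function(spec, el) {
    y0 <- y30(spec, el, kinetic_params())
    c(Mp = (y30(spec, el, kinetic_params(M_p = 755 * 1.2)) - y0) / y0,
      tau = (y30(spec, el, kinetic_params(tau = 2 * 1.2)) - y0) / y0)
  }
  s_r <- sens(small, 1)
  s_d <- sens(large, 0.3)
  expect_gt(s_r["Mp"], 0)          # more glucose per cycle -> more yield
  expect_lt(s_d["tau"], 0)         # more tortuous pores -> slower transport
  # reaction-limited: capacity dominates, tortuosity nearly irrelevant
  expect_gt(abs(s_r["Mp"]), 10 * abs(s_r["tau"]))
  # diffusion-limited: the tortuosity response is an order of magnitude larger
  expect_gt(abs(s_d["tau"]), 10 * abs(s_r["tau"]))
})

test_that("fit reports serialize to JSON", {
  fx <- fit_fixture()
  fit <- fit_hydrolysis(fx$data[c(1, 2, 4, 6), ], fx$subs, n = 14,
                        control = fit_ctl(), nstart = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$M_p, unname(coef(fit)["M_p"]), tolerance = 1e-12)
  expect_equal(nrow(rep$predictions), 4L)
  expect_true(all(c("starts", "sse", "bounds") %in% names(rep)))
})
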