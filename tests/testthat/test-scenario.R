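# Scenario configs, end-to-end runs, condition sweeps.

test_that("a degenerate sweep reproduces the single scenario", {
  sp <- ref_substrate()
  sw <- sweep_hydrolysis(sp, e_l = 1, b_l = 0.02, times_min = c(30, 60),
                         n = 14)
  sim <- simulate_hydrolysis(sp, e_l = 1, b_l = 0.02,
                             times = c(0, 30, 60), n = 14)
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$yield_fraction, sim$results$yield_fraction[-1])
  expect_equal(sw$bulk_fraction, sim$results$bulk_fraction[-1])
  expect_true(all(sw$status == "ok"))
})

test_that("sweep covers the axes product and records per-cell failures", {
  sp <- ref_substrate()
  sw <- sweep_hydrolysis(sp, e_l = c(0.5, 1), b_l = c(0.02, 2.5),
                         times_min = 30, n = 12)
  expect_equal(nrow(sw), 4L)
  # b_l = 2.5 g/cm3 is infeasible (bulk smaller than pore volume):
  # recorded, not fatal
  bad <- sw[sw$b_l == 2.5, ]
  expect_true(all(bad$status != "ok"))
  expect_true(all(is.na(bad$yield_fraction)))
  good <- sw[sw$b_l == 0.02, ]
  expect_true(all(good$status == "ok"))
})

test_that("early yield falls with particle radius along a sweep axis", {
  sw <- sweep_hydrolysis(ref_substrate(), e_l = 1, b_l = 0.02,
                         radius_cm = c(1e-3, 1e-2, 5e-2, 1e-1),
                         times_min = 60, n = 16)
  expect_true(all(diff(sw$yield_fraction[order(sw$radius_cm)]) < 0))
})

test_that("loading beyond full coverage pays off mainly for large particles", {
  gain <- function(R) {
    sw <- sweep_hydrolysis(ref_substrate(), e_l = c(1, 2), b_l = 0.02,
                           radius_cm = R, times_min = 60, n = 16)
    diff(sw$yield_fraction[order(sw$e_l)])
  }
  expect_gt(gain(0.075), 5 * gain(1.25e-3))
})

test_that("run_scenario writes results, trajectory and manifest deterministically", {
  cfg <- scenario_config(list(
    substrate = list(archetype = "severe", seed = 1),
    e_l = 1, b_l = 0.02, times_min = c(30, 60), n = 12
  ))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  sim <- run_scenario(cfg, outdir = out1)
  expect_s3_class(sim, "hydrolysis_sim")
  files <- attr(sim, "files")
  expect_true(all(file.exists(files)))
  man <- jsonlite::read_json(files[3], simplifyVector = TRUE)
  expect_equal(man$grid$n, 12L)
  expect_lt(man$conservation$max_drift, 0.02)
  expect_equal(man$conditions$e_l, 1)
  # identical config -> bitwise identical outputs
  run_scenario(cfg, outdir = out2)
  for (f in basename(files)) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
})

test_that("an enzyme-free scenario produces all-zero yield files", {
  out <- withr::local_tempdir()
  sim <- run_scenario(list(substrate = list(archetype = "mild"),
                           e_l = 0, b_l = 0.02, times_min = c(30, 60),
                           n = 12), outdir = out)
  res <- utils::read.csv(file.path(out, "results.csv"))
  expect_true(all(res$yield_fraction == 0))
})

test_that("scenario configs load from YAML with file substrates", {
  dir <- withr::local_tempdir()
  write_substrate(slab_substrate(), file.path(dir, "slab.yaml"))
  writeLines(c(
    "substrate:",
    "  path: slab.yaml",
    "e_l: 0.5",
    "b_l: 0.02",
    "times_min: [30]",
    "n: 12",
    "params:",
    "  M_p: 400"
  ), file.path(dir, "config.yaml"))
  cfg <- read_scenario(file.path(dir, "config.yaml"))
  expect_s3_class(cfg, "scenario_config")
  sim <- run_scenario(cfg, outdir = file.path(dir, "out"))
  expect_equal(sim$params$M_p, 400)
  expect_equal(sim$spec$label, "slab")
  expect_error(scenario_config(list(e_l = 1)), "substrate")
  expect_error(scenario_config(list(substrate = "x", e_l = numeric(0))),
               "non-empty")
})

test_that("the shipped example substrate and scenario run end to end", {
  sub_path <- system.file("extdata", "beech_synthetic.yaml",
                          package = "lignosim")
  sp <- read_substrate(sub_path)
  d <- derive_substrate(sp)
  expect_gt(d$surface_cm2_per_g / 1e4, 18)   # ~24 m2/g synthetic beech
  expect_lt(d$surface_cm2_per_g / 1e4, 30)
  cfg <- read_scenario(system.file("extdata", "example_scenario.yaml",
                                   package = "lignosim"))
  cfg$n <- 12                                # keep the example run light
  sim <- run_scenario(cfg, outdir = withr::local_tempdir())
  expect_true(sim$audit$ok)
  p <- read_psd_csv(system.file("extdata", "example_psd.csv",
                                package = "lignosim"))
  expect_equal(nrow(p), 6L)
})
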