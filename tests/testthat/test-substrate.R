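# Slit-pore accessibility: wall counting, additivity, derived quantities.

test_that("slit-pore wall counting follows the two-wall/one-wall/none rule", {
  # pore narrower than the enzyme: inaccessible
  acc <- accessible_surface(psd(40, 0.5))
  expect_identical(acc$surface_cm2_per_g, 0)
  expect_identical(acc$volume_cm3_per_g, 0)
  # wide pore, both walls reachable: 2 * 0.5 / 2.0e-6 cm
  acc <- accessible_surface(psd(200, 0.5))
  expect_equal(acc$surface_cm2_per_g, 5.0e5)
  expect_equal(acc$volume_cm3_per_g, 0.5)
  # intermediate pore, single wall: 0.5 / 8.0e-7 cm
  acc <- accessible_surface(psd(80, 0.5))
  expect_equal(acc$surface_cm2_per_g, 6.25e5)
  # exact boundaries go to the higher-accessibility class
  expect_equal(accessible_surface(psd(51, 0.1))$surface_cm2_per_g,
               0.1 / 51e-8)             # one wall exactly at d_E
  expect_equal(accessible_surface(psd(102, 0.1))$surface_cm2_per_g,
               2 * 0.1 / 102e-8)        # two walls exactly at 2 d_E
  # custom enzyme diameter moves the breakpoints
  expect_equal(accessible_surface(psd(80, 0.5), enzyme_diameter_angstrom = 30
               )$surface_cm2_per_g, 2 * 0.5 / 80e-8)
})

test_that("surface is additive over bins and monotone in added volume", {
  whole <- accessible_surface(psd(c(80, 200), c(0.4, 0.6)))
  # splitting one bin into two equal-volume bins at (almost) the same width
  split <- accessible_surface(psd(c(80, 199.9999, 200.0001),
                                  c(0.4, 0.3, 0.3)))
  expect_equal(split$surface_cm2_per_g, whole$surface_cm2_per_g,
               tolerance = 1e-6)
  # adding volume at any accessible width can only increase everything
  base <- psd(c(80, 200), c(0.2, 0.3))
  more <- psd(c(80, 200), c(0.2, 0.4))
  expect_gt(accessible_surface(more)$surface_cm2_per_g,
            accessible_surface(base)$surface_cm2_per_g)
  sp_b <- substrate_spec(1e-3, 0.8, 0.5, 0.5, 1.5, base)
  sp_m <- substrate_spec(1e-3, 0.8, 0.5, 0.5, 1.5, more)
  expect_gt(derive_substrate(sp_m)$eps0, derive_substrate(sp_b)$eps0)
  expect_gt(derive_substrate(sp_m)$site_density_mol_per_g,
            derive_substrate(sp_b)$site_density_mol_per_g)
})

test_that("binding-site density is surface times sigma", {
  expect_identical(binding_site_density(0), 0)
  expect_equal(binding_site_density(5.0e5, 2.1e-12), 1.05e-6)
  expect_error(binding_site_density(100, sigma_mol_per_cm2 = 0), "positive")
  expect_error(binding_site_density(-1), "negative")
})

test_that("derive_substrate computes porosities and capacity correctly", {
  d <- derive_substrate(slab_substrate())
  expect_equal(d$eps0, 0.4)                     # 0.5 cm3/g * 0.8 g/cm3
  expect_equal(d$site_density_mol_per_g, 1.05e-6)
  expect_equal(d$cs_max0_mol_per_cm3, 1.05e-6 * 0.8)
  # eps_f = eps0 + d * f_cell * rho_p / rho_C_IV
  expect_equal(d$eps_f, 0.4 + 0.8 * 0.5 * 0.8 / 1.5, tolerance = 1e-12)
  # d = 0: no hydrolyzable cellulose, eps_f = eps0
  d0 <- derive_substrate(slab_substrate(digestibility = 0))
  expect_equal(d0$eps_f, d0$eps0)
  # optional cellulose-fraction scaling halves the surface here
  dc <- derive_substrate(slab_substrate(), cellulose_only = TRUE)
  expect_equal(dc$site_density_mol_per_g, 0.5 * d$site_density_mol_per_g)
})

test_that("infeasible substrates are rejected", {
  # enormous pore volume: eps0 >= 1
  sp <- substrate_spec(1e-3, 2.0, 0.5, 0.5, 1.5, psd(200, 0.6))
  expect_error(derive_substrate(sp), "porosity >= 1")
  # feasible eps0 but exhaustion porosity beyond 1
  sp2 <- substrate_spec(1e-3, 1.4, 0.9, 1.0, 0.9, psd(200, 0.5))
  expect_error(derive_substrate(sp2), "exhaustion porosity")
})

test_that("pore size distribution validates and converts cumulative tables", {
  expect_error(psd(c(-10, 50), c(0.1, 0.1)), "strictly positive")
  expect_error(psd(c(50, 50), c(0.1, 0.1)), "strictly increasing")
  expect_error(psd(c(50, 80), c(0.1, -0.1)), "non-negative")
  expect_error(psd(numeric(0), numeric(0)), "at least one bin")
  cum <- psd(c(50, 100, 200), c(0.1, 0.3, 0.6), cumulative = TRUE)
  expect_equal(cum$volume_cm3_per_g, c(0.1, 0.2, 0.3))
  expect_error(psd(c(50, 100), c(0.3, 0.1), cumulative = TRUE),
               "non-decreasing")
  expect_equal(total_pore_volume(cum), 0.6)
})

test_that("substrate specs round-trip through YAML, JSON and PSD CSV", {
  sp <- slab_substrate()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_substrate(sp, path)
    back <- read_substrate(path)
    expect_equal(back$radius_cm, sp$radius_cm)
    expect_equal(back$digestibility, sp$digestibility)
    expect_equal(back$psd$width_angstrom, sp$psd$width_angstrom)
    expect_equal(back$psd$volume_cm3_per_g, sp$psd$volume_cm3_per_g)
    expect_equal(derive_substrate(back), derive_substrate(sp))
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(width_angstrom = c(80, 200),
                              volume_cm3_per_g = c(0.2, 0.3)),
                   csv, row.names = FALSE)
  p <- read_psd_csv(csv)
  expect_s3_class(p, "psd")
  expect_equal(nrow(p), 2L)
  expect_error(read_psd_csv(csv, cumulative = TRUE), NA)
})
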