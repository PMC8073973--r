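# Parameter containers, diffusivity, loading conversions.

test_that("effective diffusivity scales as eps * D_pore / tau", {
  expect_equal(effective_diffusivity(1, 3e-6, 1), 3e-6)
  expect_identical(effective_diffusivity(0, 3e-6, 2), 0)
  expect_equal(effective_diffusivity(0.4, 3e-6, 2), 6e-7)
  expect_error(effective_diffusivity(1.2, 3e-6, 2), "porosity")
  expect_warning(effective_diffusivity(0.5, 3e-6, 0.5), "unphysical")
})

test_that("Stokes-Einstein default matches the hand calculation", {
  # k_B * 323.15 K / (6 pi * 5.47e-4 Pa s * 2.55e-9 m), converted to cm2/min
  expect_equal(stokes_einstein_diffusivity(), 1.01815e-4, tolerance = 1e-4)
  # D ~ 1/diameter
  expect_equal(stokes_einstein_diffusivity(102),
               stokes_einstein_diffusivity(51) / 2)
})

test_that("kinetic_params validates and updates", {
  p <- kinetic_params()
  expect_equal(p$k_ads, 3e10)
  expect_equal(p$k_des, 0.068)
  expect_equal(p$sigma, 2.1e-12)
  expect_equal(p$H_glu, 0.9)
  expect_equal(p$MM_glu, 180)
  expect_error(kinetic_params(k_des = -1), "positive")
  expect_error(kinetic_params(k_ads = 0), "positive")
  expect_no_error(kinetic_params(M_p = 0))  # adsorption-only limit
  expect_warning(kinetic_params(tau = 0.5), "unphysical")
  p2 <- update_params(p, M_p = 500, tau = 3)
  expect_equal(p2$M_p, 500)
  expect_equal(p2$tau, 3)
  expect_equal(p2$k_ads, p$k_ads)
  expect_error(update_params(p, nonsense = 1), "unknown parameter")
})

test_that("site capacity declines linearly in porosity and clamps", {
  d <- derive_substrate(slab_substrate())
  expect_equal(site_capacity(d$eps0, d), d$cs_max0_mol_per_cm3)
  expect_equal(site_capacity(d$eps_f, d), 0)
  expect_equal(site_capacity((d$eps0 + d$eps_f) / 2, d),
               d$cs_max0_mol_per_cm3 / 2)
  # clamped outside the physical range (integrator overshoot)
  expect_equal(site_capacity(d$eps_f + 0.01, d), 0)
  expect_equal(site_capacity(d$eps0 - 0.01, d), d$cs_max0_mol_per_cm3)
})

test_that("Langmuir rate reproduces hand values and equilibrium", {
  expect_identical(langmuir_rate(0, 0, 1e-9, 3e10, 0.068), 0)
  expect_equal(langmuir_rate(1e-12, 0, 1e-9, 3e10, 0.068), 3e-11)
  # at the closed-form equilibrium coverage the net rate vanishes
  K <- 3e10 / 0.068
  C <- 1e-12
  theta_star <- K * C / (1 + K * C)
  expect_equal(theta_star, 0.30612, tolerance = 1e-4)
  expect_equal(langmuir_rate(C, theta_star * 1e-9, 1e-9, 3e10, 0.068), 0,
               tolerance = 1e-25)
  # over-capacity: adsorption term turns negative (net forced desorption)
  expect_lt(langmuir_rate(1e-12, 2e-9, 1e-9, 3e10, 0.068), 0)
})

test_that("porosity growth rate matches the desorption bookkeeping", {
  p <- kinetic_params(M_p = 755)
  expect_identical(porosity_rate(0, p, 1.5), 0)
  expect_equal(porosity_rate(1e-9, p, 1.5),
               0.068 * 1e-9 * 755 * 180 * 0.9 / 1.5)
  expect_equal(porosity_rate(1e-9, p, 1.5), 5.545e-6, tolerance = 1e-3)
  # forced to zero once hydrolyzable cellulose is exhausted
  expect_identical(porosity_rate(1e-9, p, 1.5, eps = 0.62, eps_f = 0.6), 0)
})

test_that("loadings convert to bulk concentration by mole balance", {
  sp <- slab_substrate()
  d <- derive_substrate(sp)
  cond <- operating_conditions(e_l = 1, b_l = 0.02, sp, d)
  # C_E0 = e_l * site_density * b_l = 1 * 1.05e-6 * 0.02
  expect_equal(cond$C_E0_mol_per_cm3, 2.1e-8)
  expect_equal(cond$V_B_cm3, 0.8 * pi * sp$radius_cm^2 / 0.02)
  expect_equal(cond$C_E0_mol_per_cm3, cond$n_E0_mol / cond$V_B_cm3)
  # e_l = 0: no enzyme
  expect_equal(operating_conditions(0, 0.02, sp, d)$C_E0_mol_per_cm3, 0)
  # doubling b_l doubles C_E0 at fixed e_l
  expect_equal(operating_conditions(1, 0.04, sp, d)$C_E0_mol_per_cm3,
               2 * cond$C_E0_mol_per_cm3)
  # loading so high the bulk cannot hold the particle pore volume
  expect_error(operating_conditions(1, 2.5, sp, d), "infeasible loading")
})

test_that("mass-based enzyme loading converts through the molar mass", {
  # 92.5 mg/g at 65 kDa = 1.423e-6 mol enzyme per g substrate
  el <- el_from_mass_loading(92.5, 1.05e-6)
  expect_equal(el, (92.5e-3 / 65000) / 1.05e-6)
  expect_equal(el_from_mass_loading(92.5, 1.05e-6,
                                    enzyme_molar_mass_g_mol = 130000),
               el / 2)
  expect_error(el_from_mass_loading(-1, 1e-6), ">= 0")
})
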