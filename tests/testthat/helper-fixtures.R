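# Shared fixtures: small, fast grids for module tests; the reference
# conditions (severe fixture, e_l = 1, b_l = 0.02 g/cm3) appear at full
# resolution only where the test is about solver accuracy itself.

ref_substrate <- function(seed = 1) synthetic_substrate("severe", seed = seed)

# One-bin slit substrate with hand-computable accessibility:
# 200 A pores, 0.5 cm3/g -> S = 5e5 cm2/g, site density 1.05e-6 mol/g,
# eps0 = 0.4 at rho_p = 0.8.
slab_substrate <- function(digestibility = 0.8) {
  substrate_spec(
    radius_cm = 1.25e-3,
    apparent_density_g_cm3 = 0.8,
    cellulose_fraction = 0.5,
    digestibility = digestibility,
    cellulose_density_g_cm3 = 1.5,
    psd = psd(200, 0.5),
    label = "slab"
  )
}

fast_sim <- function(spec, ..., n = 16) simulate_hydrolysis(spec, ..., n = n)
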