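# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture_lib <- function() {
  if (is.null(.fixtures$lib)) .fixtures$lib <- load_extinction_library()
  .fixtures$lib
}

fixture_grid <- function() wavelength_grid()

# shared Monte Carlo baseline: 1e5 photons, documented seed
fixture_baseline <- function() {
  if (is.null(.fixtures$base))
    .fixtures$base <- build_baseline(cfg = mc_config(photon_count = 1e5,
                                                     rng_seed = 42))
  .fixtures$base
}

fixture_config <- function() {
  if (is.null(.fixtures$cfg)) .fixtures$cfg <- calibrate_defaults()
  .fixtures$cfg
}

# simulate a spectrum at given endpoint levels through the shared baseline
simulate_at <- function(thb, bc, dye, musp, base = fixture_baseline(),
                        lib = fixture_lib(), grid = fixture_grid(),
                        hbsat = 0.5, b = 1.2) {
  concs <- chromophore_concentrations(HbO2 = thb * hbsat,
                                      HbH = thb * (1 - hbsat),
                                      beta_carotene = bc,
                                      patent_blue_dye = dye)
  scat <- calibrate_amplitude(musp, b = b, grid = grid)
  props <- optical_properties(grid, compose_mua(concs, lib, grid),
                              musp_power_law(scat, grid))
  simulate_spectrum(props, base = base)
}

# mastectomy-only generator config with exchangeable benign/malignant
# classes (shared rates and baselines): the null for LRT calibration checks
null_mastectomy_config <- function(n_per_class = NULL, thin_cadence = FALSE) {
  cfg <- fixture_config()
  cfg$classes$mastectomy_malignant$endpoints <-
    cfg$classes$mastectomy_benign$endpoints
  if (!is.null(n_per_class)) {
    cfg$classes$mastectomy_benign$n <- n_per_class
    cfg$classes$mastectomy_malignant$n <- n_per_class
  }
  if (thin_cadence) {
    cad <- list(first_mean = 10, first_sd = 3, first_range = c(5, 15),
                interval_range = c(0.9, 1.1), duration_range = c(10, 20))
    cfg$classes$mastectomy_benign$cadence <- cad
    cfg$classes$mastectomy_malignant$cadence <- cad
  }
  cfg
}

mastectomy_classes <- c("mastectomy_benign", "mastectomy_malignant")
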