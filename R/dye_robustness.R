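#' Factorial design of the patent-blue-dye robustness study
#'
#' Full crossing of the clinical quartile levels of band-averaged reduced
#' scattering, total hemoglobin, and beta-carotene with patent blue dye from
#' 0 to 70 uM in 10 uM steps: 3 x 3 x 3 x 8 = 216 design points, enumerated
#' exactly once in deterministic lexicographic order.
#'
#' @param mean_musp `<musp>` levels, cm^-1.
#' @param THb Total hemoglobin levels, uM.
#' @param beta_carotene Beta-carotene levels, uM.
#' @param dye Patent blue dye levels, uM.
#' @return Data frame with columns `mean_musp`, `THb`, `beta_carotene`,
#'   `dye`, one row per design point.
#' @export
build_design <- function(mean_musp = c(4.85, 6.68, 9.15),
                         THb = c(16.97, 31.03, 55.09),
                         beta_carotene = c(10.29, 16.29, 24.37),
                         dye = seq(0, 70, by = 10)) {
  d <- expand.grid(dye = dye, beta_carotene = beta_carotene, THb = THb,
                   mean_musp = mean_musp, KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("mean_musp", "THb", "beta_carotene", "dye")]
  d <- d[order(d$mean_musp, d$THb, d$beta_carotene, d$dye), , drop = FALSE]
  rownames(d) <- NULL
  if (anyDuplicated(d)) stop("design points must be unique")
  d
}

# simulate one design point and invert it with the shared library/baseline;
# returns signed percent errors for the four reported endpoints
run_design_point <- function(point, lib, base, grid, hbsat_assumption,
                             b_scatter, seed, n_starts, noise_sd = 0, ...) {
  concs <- chromophore_concentrations(
    HbO2 = point$THb * hbsat_assumption,
    HbH = point$THb * (1 - hbsat_assumption),
    beta_carotene = point$beta_carotene,
    patent_blue_dye = point$dye)
  scat <- calibrate_amplitude(point$mean_musp, b = b_scatter, grid = grid)
  props <- optical_properties(grid, compose_mua(concs, lib, grid),
                              musp_power_law(scat, grid))
  spec <- simulate_spectrum(props, base = base)
  if (noise_sd > 0) {
    vals <- spec$values * (1 + stats::rnorm(length(spec$values), 0, noise_sd))
    spec <- drs_spectrum(spec$grid, pmin(1, pmax(0, vals)),
                         provenance = "synthetic")
  }
  fit <- fit_spectrum(spec, lib, base, n_starts = n_starts, seed = seed, ...)
  ep <- fit$endpoints
  expected <- c(THb = point$THb, beta_carotene = point$beta_carotene,
                mean_musp = point$mean_musp, dye = point$dye)
  extracted <- c(THb = ep$THb, beta_carotene = ep$beta_carotene,
                 mean_musp = ep$mean_musp, dye = ep$dye)
  data.frame(endpoint = names(expected), expected = unname(expected),
             extracted = unname(extracted),
             percent_error = ifelse(expected != 0,
                                    100 * (extracted - expected) / expected,
                                    NA_real_),
             converged = fit$converged, row.names = NULL)
}

#' Run the factorial dye robustness study
#'
#' For every design point: simulate the diffuse reflectance spectrum through
#' the scaled Monte Carlo forward model, invert it with the same extinction
#' library and baseline, and record the signed percent error
#' `100 * (extracted - expected) / expected` in THb, beta-carotene, `<musp>`
#' and dye. Percent error is undefined (NA) where the expected value is 0
#' (the dye-free column); the extracted value is still recorded. The whole
#' study is deterministic given `seed`.
#'
#' @param design Data frame from [build_design()].
#' @param lib An `extinction_library`; forward and inverse stages share it.
#' @param base A `drs_baseline` (built once; the per-point scattering levels
#'   are reached by scaling).
#' @param grid A `wavelength_grid`.
#' @param hbsat_assumption Fraction of THb simulated as HbO2 (the design
#'   states THb only; 50% saturation splits it symmetrically).
#' @param b_scatter Scattering power used for the forward spectra.
#' @param seed Integer seed (start-point jitter per design point).
#' @param n_starts Fit starts per point.
#' @return Data frame of error records: design columns, `endpoint`,
#'   `expected`, `extracted`, `percent_error`, `converged`.
#' @export
run_study <- function(design = build_design(),
                      lib = load_extinction_library(),
                      base = build_baseline(), grid = wavelength_grid(),
                      hbsat_assumption = 0.5, b_scatter = 1.2, seed = 1,
                      n_starts = 5, ...) {
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    rec <- run_design_point(design[i, ], lib, base, grid, hbsat_assumption,
                            b_scatter, seed = seed + i, n_starts = n_starts,
                            ...)
    out[[i]] <- cbind(design[i, ], rec, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Liquid-phantom titration analogue
#'
#' Simulates the tissue-mimicking phantom series: a single base phantom
#' (median scattering, minimum THb and beta-carotene levels) titrated with
#' patent blue dye across `n_titrations` steps, with multiplicative Gaussian
#' measurement noise, then inverted and tabulated like [run_study()].
#'
#' @param recipe List with `mean_musp` (cm^-1), `THb`, `beta_carotene`,
#'   `dye_range` (uM). Defaults are the printed phantom recipe.
#' @param n_titrations Number of titration steps spanning `dye_range`.
#' @param noise_sd Relative (multiplicative Gaussian) noise sigma; 0.01
#'   models experimental measurement error, 0 gives the noise-free limit.
#' @param lib,base,grid,hbsat_assumption,b_scatter,seed,n_starts As in
#'   [run_study()].
#' @return Data frame of error records, one block per titration.
#' @export
run_phantom_titration <- function(recipe = list(mean_musp = 5.81,
                                                THb = 16.69,
                                                beta_carotene = 11.23,
                                                dye_range = c(0, 79)),
                                  n_titrations = 12, noise_sd = 0.01,
                                  lib = load_extinction_library(),
                                  base = build_baseline(),
                                  grid = wavelength_grid(),
                                  hbsat_assumption = 0.5, b_scatter = 1.2,
                                  seed = 1, n_starts = 5,
                                  retry_threshold = 5e-3 + 0.7 * noise_sd,
                                  objective = if (noise_sd > 0) "log"
                                              else "reflectance",
                                  ...) {
  dye <- seq(recipe$dye_range[1], recipe$dye_range[2],
             length.out = n_titrations)
  design <- data.frame(mean_musp = recipe$mean_musp, THb = recipe$THb,
                       beta_carotene = recipe$beta_carotene, dye = dye)
  set.seed(seed)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    rec <- run_design_point(design[i, ], lib, base, grid, hbsat_assumption,
                            b_scatter, seed = seed + i, n_starts = n_starts,
                            noise_sd = noise_sd,
                            retry_threshold = retry_threshold,
                            objective = objective, ...)
    out[[i]] <- cbind(design[i, ], rec, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize dye-study percent errors
#'
#' Per dye level and endpoint: mean signed percent error and maximum absolute
#' percent error, plus the count of non-converged fits (never dropped
#' silently).
#'
#' @param records Error records from [run_study()] or
#'   [run_phantom_titration()].
#' @return Data frame with one row per (dye level, endpoint).
#' @export
summarize_dye_errors <- function(records) {
  sp <- split(records, list(records$dye, records$endpoint), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    dye = d$dye[1], endpoint = d$endpoint[1],
    mean_percent_error = if (all(is.na(d$percent_error))) NA_real_
                         else mean(d$percent_error, na.rm = TRUE),
    max_abs_percent_error = if (all(is.na(d$percent_error))) NA_real_
                            else max(abs(d$percent_error), na.rm = TRUE),
    n = nrow(d), n_not_converged = sum(!d$converged))))
  out <- out[order(out$endpoint, out$dye), ]
  rownames(out) <- NULL
  out
}
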