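#' Fiber-optic probe geometry
#'
#' One channel of the imaging probe: a core of 19 illumination fibers
#' (200 um, NA 0.22) modelled as a uniformly emitting disk, surrounded by 4
#' collection fibers (200 um, NA 0.22) at a common center radius. Individual
#' source-detector separations implied by the fiber layout must stay within
#' the probe's span of 0.23-1.10 mm.
#'
#' @param illum_radius_mm Radius of the illumination core face (mm).
#' @param coll_center_mm Center radius of the collection fibers (mm).
#' @param coll_radius_mm Radius of one collection fiber face (mm).
#' @param n_coll Number of collection fibers.
#' @param na Numerical aperture (in air) of illumination and collection.
#' @param n_tissue,n_ext Refractive index of the medium and of the probe
#'   face (fiber glass).
#' @param sd_span_mm Allowed source-detector separation span (mm).
#' @return List of class `probe_geometry`.
#' @export
probe_geometry <- function(illum_radius_mm = 0.5, coll_center_mm = 0.66,
                           coll_radius_mm = 0.1, n_coll = 4, na = 0.22,
                           n_tissue = 1.37, n_ext = 1.45,
                           sd_span_mm = c(0.23, 1.10)) {
  if (na <= 0 || na >= 1) stop("NA must lie in (0, 1)")
  if (coll_radius_mm <= 0 || illum_radius_mm <= 0)
    stop("fiber dimensions must be positive")
  # outermost illumination fiber ring sits one fiber diameter inside the core
  # edge; check implied separations against the probe span
  outer_src <- illum_radius_mm - coll_radius_mm
  sep <- c(coll_center_mm - outer_src, coll_center_mm + outer_src)
  if (sep[1] < sd_span_mm[1] - 1e-9 || sep[2] > sd_span_mm[2] + 1e-9)
    stop(sprintf(
      "implied source-detector separations [%.2f, %.2f] mm exceed the probe span [%.2f, %.2f] mm",
      sep[1], sep[2], sd_span_mm[1], sd_span_mm[2]))
  structure(list(illum_radius_mm = illum_radius_mm,
                 coll_center_mm = coll_center_mm,
                 coll_radius_mm = coll_radius_mm, n_coll = n_coll, na = na,
                 n_tissue = n_tissue, n_ext = n_ext,
                 sd_separations_mm = sep),
            class = "probe_geometry")
}

#' Monte Carlo configuration
#'
#' @param photon_count Photons to launch (>= 1e3).
#' @param rng_seed Integer seed; every simulation is bit-reproducible from it.
#' @param g Henyey-Greenstein anisotropy in `[0, 1)`; the transport runs at
#'   `mus = musp / (1 - g)` so results are parameterized by `musp`
#'   (similarity).
#' @param max_path_cm Pathlength cutoff (cm).
#' @param roulette_weight,roulette_survive Russian-roulette threshold weight
#'   and survival probability.
#' @return List of class `mc_config`.
#' @export
mc_config <- function(photon_count = 1e5, rng_seed = 7041, g = 0.9,
                      max_path_cm = 5, roulette_weight = 1e-4,
                      roulette_survive = 0.1) {
  if (photon_count < 1e3) stop("photon_count must be >= 1e3")
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)")
  structure(list(photon_count = as.integer(photon_count),
                 rng_seed = as.integer(rng_seed), g = g,
                 max_path_cm = max_path_cm,
                 roulette_weight = roulette_weight,
                 roulette_survive = roulette_survive),
            class = "mc_config")
}

#' Collection profile of the probe
#'
#' Probability that a photon launched uniformly over the illumination core
#' and exiting at lateral displacement `r` (uniform azimuth, by symmetry of
#' the medium) lands on one of the collection fiber faces. Computed by
#' deterministic quadrature over launch position using the circle-circle
#' angular-overlap formula, and tabulated on a uniform `r` grid for fast
#' interpolation inside the transport kernel.
#'
#' @param geom A `probe_geometry`.
#' @param r_max_mm Largest tabulated displacement (mm).
#' @param dr_mm Table spacing (mm).
#' @param n_quad Quadrature nodes per dimension over the launch disk.
#' @return List with `dr` (mm) and `val` (profile values from r = 0).
#' @export
collection_profile <- function(geom, r_max_mm = 6.5, dr_mm = 0.005,
                               n_quad = 48) {
  # launch-point quadrature over the disk (equal-area radial nodes)
  rho <- geom$illum_radius_mm * sqrt((seq_len(n_quad) - 0.5) / n_quad)
  ang <- (seq_len(n_quad) - 0.5) / n_quad * 2 * pi
  px <- as.vector(outer(rho, cos(ang)))
  py <- as.vector(outer(rho, sin(ang)))
  # distance from each launch point to one collection fiber center
  d <- sqrt((px - geom$coll_center_mm)^2 + py^2)
  a <- geom$coll_radius_mm
  r <- seq(0, r_max_mm, by = dr_mm)
  val <- vapply(r, function(ri) {
    if (ri == 0) return(mean(d <= a))
    # azimuthal fraction of the circle of radius ri (centered on the launch
    # point) lying inside the fiber face
    arg <- (d^2 + ri^2 - a^2) / (2 * d * ri)
    frac <- ifelse(arg >= 1, 0, ifelse(arg <= -1, 1, acos(pmin(1, arg)) / pi))
    mean(frac)
  }, numeric(1))
  list(dr = dr_mm, val = val * geom$n_coll)
}

# acceptance-cone cosine inside the medium for a fiber of given NA
cone_cos <- function(na, n_medium) cos(asin(min(1, na / n_medium)))

#' Direct Monte Carlo reflectance at one wavelength
#'
#' Launches photons over the illumination face within the NA cone, transports
#' them through a homogeneous semi-infinite medium with Henyey-Greenstein
#' scattering and continuous-weight absorption, and tallies exits landing on
#' the collection fibers within the collection NA. Deterministic given the
#' seed.
#'
#' @param mua Absorption coefficient, cm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, cm^-1 (> 0).
#' @param geom A `probe_geometry`.
#' @param cfg An `mc_config`.
#' @param pcoll Optional precomputed [collection_profile()].
#' @param radial_edges_mm Optional annulus edges (mm) for a radially resolved
#'   tally of all exits (NA filter ignored), e.g. for diffusion-theory
#'   comparisons.
#' @param n_batches If > 1, the run is split into equal photon batches and a
#'   batch-means standard error of the collected reflectance is reported.
#' @return List with `collected` (dimensionless reflectance in `[0, 1]`),
#'   `total` (total diffuse reflectance), `se` (batch-means SE or NA),
#'   `radial_per_mm2` (if edges given), `n_photons`.
#' @export
run_direct_mc <- function(mua, musp, geom, cfg, pcoll = NULL,
                          radial_edges_mm = numeric(0), n_batches = 1) {
  if (!is.finite(mua) || mua < 0) stop("mua must be >= 0")
  if (!is.finite(musp) || musp <= 0) stop("musp must be > 0")
  if (is.null(pcoll)) pcoll <- collection_profile(geom)
  mus <- musp / (1 - cfg$g)
  set.seed(cfg$rng_seed)
  nb <- max(1L, as.integer(n_batches))
  per <- ceiling(cfg$photon_count / nb)
  runs <- lapply(seq_len(nb), function(i)
    mc_transport(mua = mua / 10, mus = mus / 10, g = cfg$g, n_photons = per,
                 cos_launch_min = cone_cos(geom$na, geom$n_tissue),
                 cos_accept_min = cone_cos(geom$na, geom$n_tissue),
                 n_tissue = geom$n_tissue, n_ext = geom$n_ext,
                 r_store = 0, l_max = cfg$max_path_cm * 10,
                 w_roulette = cfg$roulette_weight,
                 p_survive = cfg$roulette_survive,
                 pcoll = pcoll$val, pcoll_dr = pcoll$dr,
                 radial_edges = radial_edges_mm))
  # transport runs in mm units: mus, mua in mm^-1, lengths in mm
  cols <- vapply(runs, `[[`, numeric(1), "collected")
  out <- list(collected = mean(cols),
              total = mean(vapply(runs, `[[`, numeric(1), "total")),
              se = if (nb > 1) stats::sd(cols) / sqrt(nb) else NA_real_,
              n_photons = per * nb)
  if (length(radial_edges_mm) > 1) {
    rad <- Reduce(`+`, lapply(runs, `[[`, "radial")) / (per * nb)
    area <- pi * diff(radial_edges_mm^2)
    out$radial_per_mm2 <- rad / area
  }
  out
}

# note: mc_transport is called with mm-scaled coefficients (cm^-1 / 10) and
# mm lengths so that fiber dimensions and exit radii stay in mm throughout.

#' Build a baseline simulation for reflectance scaling
#'
#' Runs the transport once in a white (zero-absorption) medium at a reference
#' reduced scattering level and stores per-photon exit records (lateral exit
#' radius, total pathlength, weight) for every photon that exits within the
#' collection NA cone. Target optical properties are then obtained from these
#' records by similarity rescaling plus Beer-law attenuation
#' ([scale_reflectance()]), which is orders of magnitude faster than a fresh
#' simulation per wavelength. A binned (exit radius x pathlength) compression
#' of the records is precomputed for the inversion's inner loop.
#'
#' @param geom A `probe_geometry`.
#' @param cfg An `mc_config`.
#' @param musp_ref Reference reduced scattering, cm^-1 (default 6.68, the
#'   clinical median level).
#' @param mua_ref Reference absorption recorded in the metadata, cm^-1; the
#'   transport itself runs white and absorption is applied analytically.
#' @param r_store_mm Largest stored exit radius (mm); must cover the
#'   validated scaling range.
#' @param scaling_range Validated musp scaling span (factors relative to
#'   `musp_ref`).
#' @param n_r_bins,n_l_bins Compression bin counts.
#' @return List of class `drs_baseline`.
#' @export
build_baseline <- function(geom = probe_geometry(), cfg = mc_config(),
                           musp_ref = 6.68, mua_ref = 0.1, r_store_mm = 6,
                           scaling_range = c(0.25, 4),
                           n_r_bins = 120, n_l_bins = 60) {
  pcoll <- collection_profile(geom)
  mus <- musp_ref / (1 - cfg$g)
  set.seed(cfg$rng_seed)
  run <- mc_transport(mua = 0, mus = mus / 10, g = cfg$g,
                      n_photons = cfg$photon_count,
                      cos_launch_min = cone_cos(geom$na, geom$n_tissue),
                      cos_accept_min = cone_cos(geom$na, geom$n_tissue),
                      n_tissue = geom$n_tissue, n_ext = geom$n_ext,
                      r_store = r_store_mm, l_max = cfg$max_path_cm * 10,
                      w_roulette = cfg$roulette_weight,
                      p_survive = cfg$roulette_survive,
                      pcoll = pcoll$val, pcoll_dr = pcoll$dr,
                      radial_edges = numeric(0))
  rec <- run$records
  if (nrow(rec) == 0)
    stop("no photons collected: geometry or configuration fault")
  # compress: uniform radius bins x log-spaced pathlength bins,
  # weight-averaged coordinates per cell
  ri <- pmin(n_r_bins, 1L + floor(rec[, "r"] / (r_store_mm / n_r_bins)))
  lrng <- range(rec[, "L"])
  lb <- exp(seq(log(lrng[1]), log(lrng[2]), length.out = n_l_bins + 1))
  li <- pmin(n_l_bins, findInterval(rec[, "L"], lb, rightmost.closed = TRUE))
  cell <- ri + n_r_bins * (li - 1L)
  w <- tapply(rec[, "w"], cell, sum)
  cells <- list(
    r = as.numeric(tapply(rec[, "w"] * rec[, "r"], cell, sum) / w),
    L = as.numeric(tapply(rec[, "w"] * rec[, "L"], cell, sum) / w),
    w = as.numeric(w))
  structure(list(records = rec, cells = cells, pcoll = pcoll,
                 collected_white = run$collected,
                 n_photons = run$n_photons, geom = geom, cfg = cfg,
                 musp_ref = musp_ref, mua_ref = mua_ref,
                 scaling_range = scaling_range, r_store_mm = r_store_mm,
                 total_white = run$total),
            class = "drs_baseline")
}

#' Scale baseline records to target optical properties
#'
#' Applies pathlength/similarity rescaling for the target reduced scattering
#' (scale factor `s = musp_ref / musp`, shrinking both exit radius and
#' pathlength) and Beer-law attenuation `exp(-mua * s * L)` for the target
#' absorption to the stored exit records, and re-tallies collection. The
#' default path evaluates the binned compression of the records; `use_raw =
#' TRUE` evaluates every stored record.
#'
#' @param base A `drs_baseline`.
#' @param musp Target reduced scattering, cm^-1; scalar or per-wavelength
#'   vector.
#' @param mua Target absorption, cm^-1; same length as `musp`.
#' @param use_raw Evaluate raw records instead of the binned compression.
#' @param strict Error if `musp` leaves the validated scaling range
#'   (`FALSE` permits extrapolation).
#' @return Collected reflectance, same length as `musp`, in `[0, 1]`.
#' @export
scale_reflectance <- function(base, musp, mua, use_raw = FALSE,
                              strict = TRUE) {
  stopifnot(inherits(base, "drs_baseline"))
  if (length(mua) != length(musp)) stop("mua and musp lengths differ")
  if (any(!is.finite(musp)) || any(musp <= 0)) stop("musp must be > 0")
  if (any(!is.finite(mua)) || any(mua < 0)) stop("mua must be >= 0")
  fac <- musp / base$musp_ref
  if (strict && (any(fac < base$scaling_range[1] - 1e-12) ||
                 any(fac > base$scaling_range[2] + 1e-12)))
    stop(sprintf("target musp outside the validated scaling range %.3g-%.3gx of the baseline",
                 base$scaling_range[1], base$scaling_range[2]))
  s <- base$musp_ref / musp
  if (use_raw) {
    rec <- base$records
    scale_records_cpp(rec[, "r"], rec[, "L"], rec[, "w"], s, mua / 10,
                      base$pcoll$val, base$pcoll$dr, base$n_photons)
  } else {
    scale_records_cpp(base$cells$r, base$cells$L, base$cells$w, s, mua / 10,
                      base$pcoll$val, base$pcoll$dr, base$n_photons)
  }
}

#' Simulate a probe-collected diffuse reflectance spectrum
#'
#' Per-wavelength reflectance for the given optical properties via the scaled
#' baseline (or direct Monte Carlo per wavelength when no baseline is
#' supplied, much slower).
#'
#' @param props An `optical_properties`.
#' @param geom A `probe_geometry` (ignored when `base` is given).
#' @param cfg An `mc_config` (ignored when `base` is given).
#' @param base Optional `drs_baseline`.
#' @param strict Passed to [scale_reflectance()].
#' @return A `drs_spectrum`: list with `grid`, `values`, `provenance`.
#' @export
simulate_spectrum <- function(props, geom = probe_geometry(),
                              cfg = mc_config(), base = NULL,
                              strict = TRUE) {
  stopifnot(inherits(props, "optical_properties"))
  if (is.null(base)) {
    pcoll <- collection_profile(geom)
    vals <- vapply(seq_along(props$grid), function(i)
      run_direct_mc(props$mua[i], props$musp[i], geom, cfg,
                    pcoll = pcoll)$collected, numeric(1))
  } else {
    vals <- scale_reflectance(base, props$musp, props$mua, strict = strict)
  }
  drs_spectrum(props$grid, vals, provenance = "simulated")
}

#' Diffuse reflectance spectrum container
#'
#' @param grid A `wavelength_grid`.
#' @param values Dimensionless reflectance per unit incident, in `[0, 1]`.
#' @param provenance One of `"simulated"`, `"calibrated-measurement"`,
#'   `"synthetic"`.
#' @return List of class `drs_spectrum`.
#' @export
drs_spectrum <- function(grid, values,
                         provenance = c("simulated",
                                        "calibrated-measurement",
                                        "synthetic")) {
  grid <- wavelength_grid(as.numeric(grid))
  provenance <- match.arg(provenance)
  if (length(values) != length(grid)) stop("values must match the grid")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("reflectance values must be finite and within [0, 1]")
  structure(list(grid = grid, values = as.numeric(values),
                 provenance = provenance),
            class = "drs_spectrum")
}
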