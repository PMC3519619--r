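#' Wavelength grid for the analysis band
#'
#' Constructs a validated wavelength grid. All spectra in the package are
#' analyzed over 450-600 nm, the visible band in which hemoglobin,
#' beta-carotene and patent blue dye absorb and over which the reduced
#' scattering coefficient is averaged into the scalar `<musp>` endpoint.
#'
#' @param values Numeric vector of wavelengths in nm; strictly increasing.
#' @param range Allowed band, default `c(450, 600)`.
#' @return A numeric vector of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()
#' length(g)  # 31 points at 5 nm steps
#' @export
wavelength_grid <- function(values = seq(450, 600, by = 5),
                            range = c(450, 600)) {
  if (!is.numeric(values) || length(values) == 0)
    stop("wavelength grid must be a non-empty numeric vector")
  if (any(!is.finite(values)))
    stop("wavelength grid must be finite")
  if (any(diff(values) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (min(values) < range[1] || max(values) > range[2])
    stop(sprintf("wavelengths must lie within [%g, %g] nm", range[1], range[2]))
  structure(as.numeric(values), class = "wavelength_grid")
}

#' Load the packaged extinction-coefficient library
#'
#' Reads per-species molar extinction tables (two-column delimited text) and
#' their JSON sidecar declaring units and log base, and converts everything
#' to natural-log extinction in cm^-1 per uM, the internal convention. The
#' packaged tables cover oxy-hemoglobin (`HbO2`), deoxy-hemoglobin (`HbH`),
#' `beta_carotene`, and `patent_blue_dye` over 450-600 nm at 1 nm. The dye
#' curve is a synthetic approximation (a band rising toward a ~635 nm peak);
#' no published curve exists. Crocin, the phantom-study substitute for
#' beta-carotene, is represented by the beta-carotene table.
#'
#' @param dir Directory holding the tables; defaults to the installed
#'   `extdata` folder.
#' @param sidecar Name of the JSON sidecar file.
#' @return An `extinction_library`: list with `wavelength` (native grid) and
#'   `eps`, a matrix (wavelength x species) of natural-log extinction in
#'   cm^-1/uM.
#' @export
load_extinction_library <- function(dir = system.file("extdata",
                                                      package = "drsmargin"),
                                    sidecar = "extinction_meta.json") {
  meta <- jsonlite::read_json(file.path(dir, sidecar), simplifyVector = TRUE)
  species <- names(meta$species)
  tabs <- lapply(species, function(sp) {
    utils::read.delim(file.path(dir, meta$species[[sp]]))
  })
  wl <- tabs[[1]]$wavelength_nm
  for (t in tabs) {
    if (!identical(t$wavelength_nm, wl))
      stop("all species must share one native wavelength grid")
  }
  eps <- vapply(tabs, function(t) t$epsilon, numeric(length(wl)))
  colnames(eps) <- species
  # convert to natural-log extinction, cm^-1 per uM
  if (identical(meta$log_base, "decadic")) eps <- eps * log(10)
  if (identical(meta$units, "cm^-1 M^-1")) eps <- eps / 1e6
  if (any(eps < 0)) stop("extinction coefficients must be non-negative")
  structure(list(wavelength = wl, eps = eps, meta = meta),
            class = "extinction_library")
}

#' Interpolate an extinction library onto a wavelength grid
#'
#' Linear interpolation, deterministic; interpolating onto the library's own
#' native grid is the identity.
#'
#' @param lib An `extinction_library`.
#' @param grid A `wavelength_grid` (must lie within the library support).
#' @return Matrix (length(grid) x species) of natural-log extinction,
#'   cm^-1/uM.
#' @export
interp_extinction <- function(lib, grid) {
  stopifnot(inherits(lib, "extinction_library"))
  if (min(grid) < min(lib$wavelength) || max(grid) > max(lib$wavelength))
    stop("grid lies outside the extinction library support")
  out <- apply(lib$eps, 2, function(e)
    stats::approx(lib$wavelength, e, xout = as.numeric(grid))$y)
  rownames(out) <- as.character(as.numeric(grid))
  out
}

#' Chromophore concentrations
#'
#' @param HbO2,HbH,beta_carotene,patent_blue_dye Concentrations in uM,
#'   all non-negative.
#' @return Named numeric vector of class `chromophore_concentrations`.
#' @export
chromophore_concentrations <- function(HbO2 = 0, HbH = 0, beta_carotene = 0,
                                       patent_blue_dye = 0) {
  x <- c(HbO2 = HbO2, HbH = HbH, beta_carotene = beta_carotene,
         patent_blue_dye = patent_blue_dye)
  if (any(!is.finite(x)) || any(x < 0))
    stop("concentrations must be finite and non-negative")
  structure(x, class = "chromophore_concentrations")
}

#' Compose the absorption coefficient from chromophore concentrations
#'
#' Beer's law: `mua(lambda) = sum_i eps_i(lambda) * c_i`, with the library
#' already converted to natural-log extinction (cm^-1/uM), so no base factor
#' is applied here; the loader honors the declared log base of the source
#' tables.
#'
#' @param concs A `chromophore_concentrations` (uM).
#' @param lib An `extinction_library`.
#' @param grid A `wavelength_grid`.
#' @return Numeric vector, `mua(lambda)` in cm^-1.
#' @export
compose_mua <- function(concs, lib, grid) {
  E <- interp_extinction(lib, grid)
  missing <- setdiff(names(concs), colnames(E))
  if (length(missing))
    stop("species missing from library: ", paste(missing, collapse = ", "))
  as.numeric(E[, names(concs), drop = FALSE] %*% as.numeric(concs))
}

#' Scattering parameters for the power-law model
#'
#' `musp(lambda) = a * (lambda / lambda0)^(-b)` with amplitude `a` (cm^-1 at
#' the 500 nm reference) and dimensionless power `b`.
#'
#' @param a Amplitude in cm^-1 at `lambda0`; positive.
#' @param b Scattering power; non-negative.
#' @param lambda0 Reference wavelength in nm.
#' @return List of class `scattering_params`.
#' @export
scattering_params <- function(a, b = 1.2, lambda0 = 500) {
  if (!is.finite(a) || a <= 0) stop("scattering amplitude a must be > 0")
  if (!is.finite(b) || b < 0) stop("scattering power b must be >= 0")
  structure(list(a = a, b = b, lambda0 = lambda0),
            class = "scattering_params")
}

#' Evaluate the reduced scattering spectrum
#'
#' @param params A `scattering_params`.
#' @param grid A `wavelength_grid`.
#' @return `musp(lambda)` in cm^-1 (strictly positive).
#' @export
musp_power_law <- function(params, grid) {
  stopifnot(inherits(params, "scattering_params"))
  params$a * (as.numeric(grid) / params$lambda0)^(-params$b)
}

#' Calibrate the scattering amplitude to a target band-averaged musp
#'
#' Solves for the amplitude `a` such that the mean of `musp(lambda)` over the
#' grid equals `target_mean_musp` -- the scalar `<musp>` endpoint is defined
#' as this 450-600 nm average.
#'
#' @param target_mean_musp Target `<musp>` in cm^-1; positive.
#' @param b Scattering power.
#' @param grid A `wavelength_grid`.
#' @param lambda0 Reference wavelength in nm.
#' @return A `scattering_params` whose band average equals the target
#'   (relative error < 1e-9).
#' @export
calibrate_amplitude <- function(target_mean_musp, b = 1.2,
                                grid = wavelength_grid(), lambda0 = 500) {
  if (!is.finite(target_mean_musp) || target_mean_musp <= 0)
    stop("target mean musp must be > 0")
  shape <- mean((as.numeric(grid) / lambda0)^(-b))
  scattering_params(a = target_mean_musp / shape, b = b, lambda0 = lambda0)
}

#' Optical properties on a wavelength grid
#'
#' @param grid A `wavelength_grid`.
#' @param mua Absorption coefficient spectrum, cm^-1 (non-negative).
#' @param musp Reduced scattering spectrum, cm^-1 (positive).
#' @return List of class `optical_properties`.
#' @export
optical_properties <- function(grid, mua, musp) {
  grid <- wavelength_grid(as.numeric(grid))
  if (length(mua) != length(grid) || length(musp) != length(grid))
    stop("mua and musp must match the grid length")
  if (any(!is.finite(mua)) || any(mua < 0)) stop("mua must be >= 0")
  if (any(!is.finite(musp)) || any(musp <= 0)) stop("musp must be > 0")
  structure(list(grid = grid, mua = as.numeric(mua), musp = as.numeric(musp)),
            class = "optical_properties")
}
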