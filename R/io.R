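#' Write spectra to delimited text
#'
#' One header row of wavelengths, one row per (site, timepoint) with leading
#' metadata columns (`site_id`, `specimen_type`, `histology`,
#' `minutes_post_excision`), then the reflectance values.
#'
#' @param spectra List of `drs_spectrum` (shared grid).
#' @param meta Data frame of metadata, one row per spectrum.
#' @param file Output path.
#' @export
write_spectra <- function(spectra, meta, file) {
  grid <- spectra[[1]]$grid
  for (s in spectra)
    if (!identical(as.numeric(s$grid), as.numeric(grid)))
      stop("all spectra must share one wavelength grid")
  vals <- do.call(rbind, lapply(spectra, `[[`, "values"))
  # full precision so written spectra survive a read round trip bit-exactly
  vals <- apply(vals, 2, function(v) sprintf("%.17g", v))
  vals <- matrix(vals, nrow = length(spectra))
  colnames(vals) <- sprintf("wl_%.10g", as.numeric(grid))
  utils::write.csv(cbind(meta, as.data.frame(vals)), file,
                   row.names = FALSE, quote = FALSE)
}

#' Read spectra written by [write_spectra()]
#'
#' @param file Input path.
#' @param provenance Provenance tag to assign.
#' @return List with `spectra` (list of `drs_spectrum`) and `meta`.
#' @export
read_spectra <- function(file, provenance = "calibrated-measurement") {
  d <- utils::read.csv(file, check.names = FALSE)
  wcols <- grep("^wl_", names(d))
  grid <- wavelength_grid(as.numeric(sub("^wl_", "", names(d)[wcols])))
  spectra <- lapply(seq_len(nrow(d)), function(i)
    drs_spectrum(grid, as.numeric(d[i, wcols]), provenance = provenance))
  list(spectra = spectra, meta = d[, -wcols, drop = FALSE])
}

#' Write a tidy endpoint table
#'
#' One row per (site, timepoint) with metadata and all endpoint fields, the
#' schema shared by the inversion output and the synthetic generator.
#'
#' @param data Data frame (e.g. `cohort$data`).
#' @param file Output path.
#' @export
write_endpoints <- function(data, file) {
  utils::write.csv(data, file, row.names = FALSE, quote = FALSE)
}

#' Read a tidy endpoint table
#' @param file Input path.
#' @return Data frame.
#' @export
read_endpoints <- function(file) utils::read.csv(file)
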