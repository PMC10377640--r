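#' Chromophore absorption spectra
#'
#' Loads the tabulated absorption coefficients (1/cm) of the tissue
#' chromophores used to mix per-layer absorption: oxyhemoglobin and
#' deoxyhemoglobin (as whole blood at 150 g Hb/L), water, fat, melanin
#' (melanosome interior), bloodless skin baseline and collagen.
#'
#' The shipped default table is a literature-based compilation covering
#' 600--1000 nm, including the two oximetry wavelengths 660 nm and 940 nm
#' exactly.  A user table can be supplied as a plain-text columnar file with
#' a `wavelength_nm` column and one column per chromophore.
#'
#' @param path Optional path to a tab-separated spectra file.  Default: the
#'   table shipped with the package.
#' @return A data frame of class `chromophore_spectra` with one row per
#'   tabulated wavelength.
#' @export
chromophore_spectra <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chromophore_mua.tsv", package = "rpoxim")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = TRUE)
  if (!"wavelength_nm" %in% names(tab)) {
    stop("spectra file must have a 'wavelength_nm' column")
  }
  if (any(as.matrix(tab) < 0)) stop("absorption coefficients must be >= 0")
  if (is.unsorted(tab$wavelength_nm, strictly = TRUE)) {
    tab <- tab[order(tab$wavelength_nm), , drop = FALSE]
  }
  need <- c(660, 940)
  rng <- range(tab$wavelength_nm)
  if (any(need < rng[1] | need > rng[2])) {
    stop("spectra table must cover 660 nm and 940 nm")
  }
  class(tab) <- c("chromophore_spectra", "data.frame")
  tab
}

#' Look up a chromophore absorption coefficient
#'
#' Linear interpolation between tabulated wavelengths; a lookup at a
#' tabulated wavelength returns the tabulated value exactly.
#'
#' @param spectra A [chromophore_spectra()] table.
#' @param chromophore Column name, e.g. `"oxy_hb"`, `"water"`.
#' @param wavelength_nm Wavelength in nm (scalar or vector).
#' @return Absorption coefficient(s) in 1/cm.
#' @export
mua_lookup <- function(spectra, chromophore, wavelength_nm) {
  if (!chromophore %in% names(spectra)) {
    stop("unknown chromophore: ", chromophore)
  }
  wl <- spectra$wavelength_nm
  if (any(wavelength_nm < min(wl) | wavelength_nm > max(wl))) {
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm",
                 min(wl), max(wl)))
  }
  stats::approx(wl, spectra[[chromophore]], xout = wavelength_nm,
                method = "linear", ties = "ordered")$y
}

#' @export
print.chromophore_spectra <- function(x, ...) {
  cat("Chromophore absorption spectra (1/cm):",
      ncol(x) - 1L, "chromophores,",
      nrow(x), "wavelengths spanning",
      sprintf("%g-%g nm\n", min(x$wavelength_nm), max(x$wavelength_nm)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
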