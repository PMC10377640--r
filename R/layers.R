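#' Tissue layer identifiers, ordered outermost skin shell first
#' @keywords internal
LAYER_IDS <- c("epidermis", "papillary_dermis", "upper_blood_net_dermis",
               "reticular_dermis", "deep_blood_net_dermis",
               "subcutaneous_fat", "bone", "artery_blood")

#' Default per-layer tissue compositions and scattering properties
#'
#' One row per tissue compartment: chromophore volume fractions (`f_*`),
#' scattering coefficient at 660 and 940 nm (1/cm), Henyey-Greenstein
#' anisotropy `g`, refractive index `n`, and (for the skin shells) the shell
#' thickness in cm.  Subcutaneous fat fills the remainder of the soft tissue;
#' bone and the arteries override it spatially.
#'
#' Values are literature-typical defaults for fair-to-medium skin
#' (blood/water fractions per dermal sublayer follow the usual seven-layer
#' skin-optics compilations); every entry can be overridden via
#' configuration.  `capillary` flags the compartments whose blood fraction is
#' scaled by the cardiac-phase capillary multiplier (the arteries pulse by
#' radius instead).
#'
#' @return A data frame of class `layer_composition`.
#' @export
layer_compositions <- function() {
  tab <- data.frame(
    layer       = LAYER_IDS,
    f_blood     = c(0.00, 0.02, 0.15, 0.04, 0.10, 0.05, 0.03, 1.00),
    f_water     = c(0.20, 0.50, 0.50, 0.60, 0.60, 0.05, 0.25, 0.00),
    f_fat       = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.80, 0.20, 0.00),
    f_melanin   = c(0.02, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    f_baseline  = c(0.78, 0.16, 0.05, 0.03, 0.05, 0.05, 0.17, 0.00),
    f_collagen  = c(0.00, 0.30, 0.20, 0.30, 0.20, 0.00, 0.30, 0.00),
    mus_660     = c(300, 250, 250, 250, 250, 120, 350, 700),
    mus_940     = c(220, 180, 180, 180, 180, 100, 280, 580),
    g           = c(0.90, 0.85, 0.85, 0.85, 0.85, 0.90, 0.92, 0.98),
    n           = c(1.40, 1.39, 1.39, 1.40, 1.39, 1.44, 1.55, 1.38),
    thickness_cm = c(0.010, 0.020, 0.008, 0.080, 0.030, NA, NA, NA),
    capillary   = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  validate_compositions(tab)
  class(tab) <- c("layer_composition", "data.frame")
  tab
}

#' @keywords internal
validate_compositions <- function(tab) {
  frac_cols <- grep("^f_", names(tab), value = TRUE)
  fr <- as.matrix(tab[, frac_cols])
  if (any(fr < 0 | fr > 1)) stop("volume fractions must lie in [0, 1]")
  if (any(rowSums(fr) > 1 + 1e-9)) {
    stop("volume fractions must sum to <= 1 per layer")
  }
  if (any(tab$mus_660 < 0) || any(tab$mus_940 < 0)) stop("mu_s must be >= 0")
  if (any(tab$g <= -1 | tab$g >= 1)) stop("anisotropy g must lie in (-1, 1)")
  if (any(tab$n < 1)) stop("refractive index must be >= 1")
  invisible(tab)
}

#' Scattering coefficient of a layer at a wavelength
#'
#' Log-linear interpolation between the tabulated 660 and 940 nm values
#' (power-law wavelength dependence typical of tissue scattering).
#' @keywords internal
mus_at <- function(row, wavelength_nm) {
  if (wavelength_nm == 660) return(row$mus_660)
  if (wavelength_nm == 940) return(row$mus_940)
  if (row$mus_660 <= 0 || row$mus_940 <= 0) return(0)
  b <- log(row$mus_940 / row$mus_660) / log(940 / 660)
  row$mus_660 * (wavelength_nm / 660)^b
}

#' Mix the absorption coefficient of a tissue layer
#'
#' Volume-fraction mixing of chromophore absorption: `mu_a = sum_i f_i *
#' mu_a,i(lambda)`, where the blood fraction is split between oxy- and
#' deoxyhemoglobin by the oxygen saturation and scaled by the cardiac-phase
#' capillary blood-volume multiplier:
#' `f_blood * m * (spo2 * mua_HbO2 + (1 - spo2) * mua_Hb)`.
#'
#' @param composition One row of a [layer_compositions()] table (or a list
#'   with the same `f_*` fields).
#' @param spectra A [chromophore_spectra()] table.
#' @param wavelength_nm Wavelength (nm), inside the tabulated range.
#' @param spo2 Oxygen saturation fraction in \[0, 1\].
#' @param phase_multiplier Capillary blood-volume multiplier (> 0); scales
#'   only the blood fraction.
#' @return Absorption coefficient in 1/cm.
#' @export
mix_absorption <- function(composition, spectra, wavelength_nm, spo2 = 0.98,
                           phase_multiplier = 1) {
  stopifnot(spo2 >= 0, spo2 <= 1, phase_multiplier > 0)
  f <- function(name) {
    v <- composition[[name]]
    if (is.null(v) || is.na(v)) 0 else v
  }
  f_blood_eff <- f("f_blood") * phase_multiplier
  total <- f_blood_eff + f("f_water") + f("f_fat") + f("f_melanin") +
    f("f_baseline") + f("f_collagen")
  if (total > 1 + 1e-9) {
    stop("scaled volume fractions exceed 1 (phase multiplier too large)")
  }
  mua_blood <- spo2 * mua_lookup(spectra, "oxy_hb", wavelength_nm) +
    (1 - spo2) * mua_lookup(spectra, "deoxy_hb", wavelength_nm)
  mua <- f_blood_eff * mua_blood +
    f("f_water")    * mua_lookup(spectra, "water",    wavelength_nm) +
    f("f_fat")      * mua_lookup(spectra, "fat",      wavelength_nm) +
    f("f_melanin")  * mua_lookup(spectra, "melanin",  wavelength_nm) +
    f("f_baseline") * mua_lookup(spectra, "baseline", wavelength_nm) +
    f("f_collagen") * mua_lookup(spectra, "collagen", wavelength_nm)
  as.numeric(mua)
}
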