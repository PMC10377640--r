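#' Build a tissue map: geometry plus resolved optical properties
#'
#' Resolves, for one wavelength and one physiological state, the absorption
#' coefficient, scattering coefficient, anisotropy and refractive index of
#' every tissue compartment, together with the spatial classification rule
#' (artery > bone > skin shell by radial depth > subcutaneous fat).  The
#' result is the self-contained input of [run_simulation()].
#'
#' @param geometry A [finger_geometry()].
#' @param compositions A [layer_compositions()] table (one row per layer id).
#' @param spectra A [chromophore_spectra()] table.
#' @param state A [physiological_state()].
#' @param wavelength_nm Wavelength in nm.
#' @return An object of class `tissue_map`.
#' @export
build_tissue_map <- function(geometry = finger_geometry(),
                             compositions = layer_compositions(),
                             spectra = chromophore_spectra(),
                             state = physiological_state(),
                             wavelength_nm = 660) {
  if (!setequal(compositions$layer, LAYER_IDS)) {
    stop("compositions must contain exactly one row per layer id: ",
         paste(LAYER_IDS, collapse = ", "))
  }
  validate_geometry(geometry, artery_radius_cm = state$artery_radius_cm)
  idx <- match(LAYER_IDS, compositions$layer)
  comp <- compositions[idx, , drop = FALSE]

  mua <- mus <- g <- n <- numeric(length(LAYER_IDS))
  for (i in seq_along(LAYER_IDS)) {
    row <- comp[i, , drop = FALSE]
    m <- if (row$capillary) state$capillary_multiplier else 1
    mua[i] <- mix_absorption(row, spectra, wavelength_nm, state$spo2, m)
    mus[i] <- mus_at(row, wavelength_nm)
    g[i] <- row$g
    n[i] <- row$n
  }

  structure(list(
    geometry = geometry,
    state = state,
    wavelength_nm = wavelength_nm,
    layers = LAYER_IDS,
    mua = mua, mus = mus, g = g, n = n,
    # cumulative shell boundary depths from the outer surface, cm
    shell_depths = cumsum(unname(geometry$skin_thickness_cm))
  ), class = "tissue_map")
}

#' Classify 3D points into tissue compartments
#'
#' Deterministic spatial query backing the transport kernel.  Priority:
#' artery > bone > skin shell by radial depth > subcutaneous fat; points at
#' radial distance beyond the finger radius (or beyond the end caps) are
#' classified `"surround"`.
#'
#' @param map A [build_tissue_map()] result.
#' @param points Numeric matrix with columns x, y, z (cm), or a length-3
#'   vector for a single point.
#' @return Character vector of layer ids (or `"surround"`).
#' @export
classify_point <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  stopifnot(ncol(points) == 3)
  geom <- map$geometry
  codes <- cpp_classify(points,
                        geom$radius_cm,
                        map$shell_depths,
                        geom$bone_center_cm[1], -geom$bone_center_cm[2],
                        geom$bone_semiaxes_cm[1], geom$bone_semiaxes_cm[2],
                        geom$artery_center_cm[1], -geom$artery_center_cm[2],
                        map$state$artery_radius_cm,
                        geom$length_cm / 2)
  c("surround", map$layers)[codes + 1L]
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("Tissue map: %s state, SpO2 %.0f%%, %g nm\n",
              x$state$phase, 100 * x$state$spo2, x$wavelength_nm))
  props <- data.frame(layer = x$layers, mua_per_cm = round(x$mua, 4),
                      mus_per_cm = round(x$mus, 1), g = x$g, n = x$n)
  print(props, row.names = FALSE)
  invisible(x)
}
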