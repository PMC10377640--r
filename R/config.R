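#' Default experiment configuration
#'
#' A nested list mirroring the reference setup field-for-field: geometry
#' (ring diameter 1.7 cm, bone and vessel placement), cardiac-phase
#' parameters, sweep section (PD angles 25--95 deg step 5, wavelengths 660
#' and 940 nm, SpO2 levels 70--100%, surround reflectances 0 and 1), photon
#' count, repeat count and seed.  All physical quantities carry explicit
#' units in their key names.
#'
#' @return A list of class `rpo_config`.
#' @export
rpo_default_config <- function() {
  structure(list(
    geometry = list(
      ring_diameter_cm = 1.7,
      bone_center_cm = c(0, 0.3),
      bone_size_cm = c(0.5, 0.3),
      artery_center_cm = c(0.4, 0.45),
      artery_radius_cm = 0.08,
      skin_thickness_cm = list(
        epidermis = 0.010, papillary_dermis = 0.020,
        upper_blood_net_dermis = 0.008, reticular_dermis = 0.080,
        deep_blood_net_dermis = 0.030),
      length_cm = 4.0,
      pd_size_cm = c(0.3, 0.3),
      led_radius_cm = 0.15),
    physiology = list(
      spo2 = 0.98,
      systolic = list(artery_radius_cm = 0.080, capillary_multiplier = 1.0),
      diastolic = list(artery_radius_cm = 0.092, capillary_multiplier = 1.5)),
    source = list(wavelength_nm = 660, profile = "lambertian"),
    detector = list(theta_deg = 25),
    boundary = list(rho = 0),
    sweep = list(
      theta_deg = seq(25, 95, by = 5),
      wavelengths_nm = c(660, 940),
      spo2 = c(0.70, 0.80, 0.90, 1.00),
      rho = c(0, 1),
      n_photons = 1e5,
      n_repeats = 1),
    n_photons = 1e5,
    seed = 1,
    spectra_path = NULL,
    out_dir = "."
  ), class = "rpo_config")
}

#' Read / validate an experiment configuration
#'
#' YAML configuration merged over the defaults; unknown top-level fields
#' are rejected with their field path.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list (or `key=value` character vector) of
#'   overrides applied last, with keys as dotted paths
#'   (e.g. `boundary.rho`).
#' @return A validated `rpo_config`.
#' @export
read_rpo_config <- function(path = NULL, overrides = NULL) {
  cfg <- rpo_default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, prefix = character())
  }
  if (!is.null(overrides)) {
    if (is.character(overrides)) {
      kv <- strsplit(overrides, "=", fixed = TRUE)
      overrides <- stats::setNames(
        lapply(kv, function(x) type_guess(x[2])),
        vapply(kv, `[`, "", 1))
    }
    for (key in names(overrides)) {
      cfg <- set_path(cfg, strsplit(key, ".", fixed = TRUE)[[1]],
                      overrides[[key]])
    }
  }
  validate_config(cfg)
}

#' @keywords internal
type_guess <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

#' @keywords internal
merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    path <- c(prefix, key)
    if (!key %in% names(base)) {
      stop("unknown configuration field: ", paste(path, collapse = "."))
    }
    if (is.list(base[[key]]) && is.list(user[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]], path)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' @keywords internal
set_path <- function(cfg, keys, value) {
  if (!keys[1] %in% names(cfg)) {
    stop("unknown configuration field: ", keys[1])
  }
  if (length(keys) == 1) {
    cfg[[keys]] <- value
  } else {
    cfg[[keys[1]]] <- set_path(cfg[[keys[1]]], keys[-1], value)
  }
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  req <- function(cond, field, msg) {
    if (!cond) stop(sprintf("config field '%s': %s", field, msg))
  }
  g <- cfg$geometry
  for (f in c("ring_diameter_cm", "bone_center_cm", "bone_size_cm",
              "artery_center_cm", "artery_radius_cm", "skin_thickness_cm",
              "length_cm", "pd_size_cm", "led_radius_cm")) {
    req(!is.null(g[[f]]), paste0("geometry.", f), "missing required field")
  }
  req(g$ring_diameter_cm > 0, "geometry.ring_diameter_cm", "must be > 0")
  req(cfg$boundary$rho >= 0 && cfg$boundary$rho <= 1, "boundary.rho",
      "must lie in [0, 1]")
  req(all(cfg$sweep$spo2 >= 0 & cfg$sweep$spo2 <= 1), "sweep.spo2",
      "must lie in [0, 1]")
  req(cfg$n_photons >= 1, "n_photons", "must be >= 1")
  # building the geometry object runs the geometric consistency checks
  config_geometry(cfg)
  cfg
}

#' @keywords internal
config_geometry <- function(cfg) {
  g <- cfg$geometry
  finger_geometry(
    ring_diameter_cm = g$ring_diameter_cm,
    bone_center_cm = unlist(g$bone_center_cm),
    bone_size_cm = unlist(g$bone_size_cm),
    artery_center_cm = unlist(g$artery_center_cm),
    artery_radius_cm = g$artery_radius_cm,
    skin_thickness_cm = unlist(g$skin_thickness_cm),
    length_cm = g$length_cm,
    pd_size_cm = unlist(g$pd_size_cm),
    led_radius_cm = g$led_radius_cm)
}

#' Write a configuration to YAML
#' @param cfg An `rpo_config`.
#' @param path Output path.
#' @export
write_rpo_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
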