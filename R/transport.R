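#' LED source configuration
#'
#' @param wavelength_nm Emission wavelength (must match the tissue map used).
#' @param theta_deg Angular position of the LED center along the rim
#'   (degrees; 0 = bottom of the cross-section).
#' @param led_radius_cm Radius of the emitting disk on the finger surface.
#' @param profile Emission profile: `"lambertian"` (inward cosine-weighted)
#'   or `"pencil"` (single ray along the inward surface normal).
#' @return An object of class `source_config`.
#' @export
source_config <- function(wavelength_nm = 660, theta_deg = 0,
                          led_radius_cm = 0.15,
                          profile = c("lambertian", "pencil")) {
  profile <- match.arg(profile)
  structure(list(wavelength_nm = wavelength_nm, theta_deg = theta_deg,
                 led_radius_cm = led_radius_cm, profile = profile),
            class = "source_config")
}

#' Photodetector configuration
#'
#' A rectangular aperture tangent to the finger surface, centered at angular
#' separation `theta_deg` from the rim origin in the source's axial plane.
#' All arrival angles are accepted.
#'
#' @param theta_deg Angular position of the PD center (degrees; the
#'   reference sweeps use 25--95).
#' @param aperture_cm Aperture (arc width, axial height) in cm.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(theta_deg = 25, aperture_cm = c(0.3, 0.3)) {
  structure(list(theta_deg = theta_deg, aperture_cm = aperture_cm),
            class = "detector_config")
}

#' Surround boundary configuration
#'
#' The ring surround is modelled as a probabilistic specular mirror:
#' a photon crossing the finger surface outside the PD aperture is
#' specularly reflected with probability `rho` and otherwise absorbed.
#' `rho = 0` is the ideal absorber (RPO-NR), `rho = 1` the ideal mirror
#' (RPO-R).
#'
#' @param rho Surround reflectance in \[0, 1\].
#' @return An object of class `boundary_config`.
#' @export
boundary_config <- function(rho = 0) {
  stopifnot(rho >= 0, rho <= 1)
  structure(list(rho = rho), class = "boundary_config")
}

#' Run a Monte Carlo photon-transport simulation
#'
#' Transports `n_photons` weighted photon packets from the LED through the
#' tissue map to the PD, with Henyey-Greenstein scattering, survival-weight
#' absorption, Russian roulette (threshold 1e-4, survival 0.1), exact
#' ray-cylinder surface crossings, absorbing end caps, and the configured
#' surround reflectance.  Runs are bitwise reproducible for a fixed seed.
#'
#' @param map A [build_tissue_map()] result.
#' @param source A [source_config()]; its wavelength must equal the map's.
#' @param detector A [detector_config()], or `NULL` for no detector.
#' @param boundary A [boundary_config()].
#' @param n_photons Number of photon packets (>= 1).
#' @param seed Integer seed for the kernel's own RNG stream.
#' @param fluence If `TRUE`, accumulate a cross-sectional map of absorbed
#'   weight (projected along the cylinder axis).
#' @param fluence_n Fluence grid resolution per axis.
#' @return An object of class `transport_result`: detected weight fraction
#'   `I`, the energy-balance `ledger` (tissue, surround, end caps, roulette
#'   net), photon count and seed, and optionally the `fluence` matrix.
#' @export
run_simulation <- function(map, source = source_config(),
                           detector = detector_config(),
                           boundary = boundary_config(),
                           n_photons = 1e5, seed = 1,
                           fluence = FALSE, fluence_n = 200) {
  stopifnot(inherits(map, "tissue_map"), n_photons >= 1)
  if (!is.null(source$wavelength_nm) &&
      source$wavelength_nm != map$wavelength_nm) {
    stop("source wavelength does not match the tissue map wavelength")
  }
  if (any(map$mua + map$mus <= 0)) {
    # a zero-mu_t layer is only valid as an explicit vacuum-like override
    if (any(map$mua < 0) || any(map$mus < 0)) stop("invalid property table")
  }
  geom <- map$geometry
  det_enabled <- !is.null(detector)
  det_theta <- if (det_enabled) detector$theta_deg * pi / 180 else 0
  det_half_arc <- if (det_enabled) detector$aperture_cm[1] / 2 else 0
  det_half_z <- if (det_enabled) detector$aperture_cm[2] / 2 else 0

  res <- cpp_run_simulation(
    geom$radius_cm, map$shell_depths, geom$length_cm / 2,
    geom$bone_center_cm[1], -geom$bone_center_cm[2],
    geom$bone_semiaxes_cm[1], geom$bone_semiaxes_cm[2],
    geom$artery_center_cm[1], -geom$artery_center_cm[2],
    map$state$artery_radius_cm,
    map$mua, map$mus, map$g,
    source$theta_deg * pi / 180, source$led_radius_cm,
    if (source$profile == "pencil") 1L else 0L,
    det_theta, det_half_arc, det_half_z, det_enabled,
    boundary$rho, as.numeric(n_photons), as.integer(seed),
    1e-4, 0.1,
    if (fluence) as.integer(fluence_n) else 0L)

  structure(list(
    I = res$detected,
    ledger = c(detected = res$detected, tissue = res$tissue,
               surround = res$surround, caps = res$caps,
               roulette_net = res$roulette_net),
    n_detected_events = res$n_detected_events,
    n_photons = res$n_photons,
    seed = as.integer(seed),
    wavelength_nm = map$wavelength_nm,
    theta_deg = if (det_enabled) detector$theta_deg else NA_real_,
    rho = boundary$rho,
    state = map$state,
    fluence = res$fluence
  ), class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo transport: N = %g photons, seed %d, %g nm, rho = %g\n",
    x$n_photons, x$seed, x$wavelength_nm, x$rho))
  if (!is.na(x$theta_deg)) {
    cat(sprintf("  PD at theta_PL = %g deg\n", x$theta_deg))
  }
  cat(sprintf("  detected fraction I = %.4g (%.4g%% of launched weight)\n",
              x$I, 100 * x$I))
  cat("  ledger:", paste(sprintf("%s %.4g", names(x$ledger), x$ledger),
                         collapse = ", "), "\n")
  cat(sprintf("  conservation residual: %.2e\n", 1 - sum(x$ledger)))
  invisible(x)
}

# ---- elementary transport operations (same samplers as the kernel) --------

#' Sample free-path step lengths
#'
#' `s = -log(xi) / mu_t`, exponentially distributed with mean `1/mu_t`,
#' drawn from the kernel's own RNG stream.
#'
#' @param n Number of samples.
#' @param mu_t Total attenuation coefficient (1/cm), > 0.
#' @param seed Integer seed.
#' @return Numeric vector of step lengths (cm).
#' @export
step_length <- function(n, mu_t, seed = 1) {
  if (mu_t <= 0) stop("mu_t must be positive in a non-vacuum layer")
  cpp_exp_samples(as.integer(n), mu_t, as.integer(seed))
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Inverse-CDF sampling of the scattering deflection cosine used by the
#' kernel's spin step; for `g = 0` the cosine is uniform on \[-1, 1\].
#'
#' @param n Number of samples.
#' @param g Anisotropy in (-1, 1).
#' @param seed Integer seed.
#' @return Numeric vector of deflection cosines.
#' @export
hg_cosines <- function(n, g, seed = 1) {
  cpp_hg_samples(as.integer(n), g, as.integer(seed))
}

#' Sample launch states from the LED source
#'
#' @param n Number of photons.
#' @param geometry A [finger_geometry()].
#' @param source A [source_config()].
#' @param seed Integer seed.
#' @return Matrix with columns x, y, z, ux, uy, uz.
#' @export
launch_photons <- function(n, geometry = finger_geometry(),
                           source = source_config(), seed = 1) {
  m <- cpp_launch_samples(as.integer(n), as.integer(seed),
                          geometry$radius_cm,
                          source$theta_deg * pi / 180,
                          source$led_radius_cm,
                          if (source$profile == "pencil") 1L else 0L)
  colnames(m) <- c("x", "y", "z", "ux", "uy", "uz")
  m
}

#' Deterministic survival-weight drop
#'
#' `Delta W = W * mu_a / mu_t`; the photon keeps `W * (1 - mu_a/mu_t)`.
#'
#' @param w Current photon weight(s).
#' @param mu_a Absorption coefficient (1/cm).
#' @param mu_t Total attenuation coefficient (1/cm), `mu_a <= mu_t`.
#' @return List with `w` (new weight) and `absorbed`.
#' @export
drop_weight <- function(w, mu_a, mu_t) {
  if (any(mu_a < 0) || any(mu_a > mu_t)) {
    stop("require 0 <= mu_a <= mu_t")
  }
  absorbed <- w * mu_a / mu_t
  list(w = w - absorbed, absorbed = absorbed)
}

#' Specular reflection about a surface normal
#'
#' Mirror law used at the reflective surround: the normal component of the
#' direction is negated, tangential components are preserved.
#'
#' @param direction Unit direction vector (length 3).
#' @param normal Outward unit surface normal (length 3).
#' @return Reflected unit direction.
#' @export
reflect_direction <- function(direction, normal) {
  direction - 2 * sum(direction * normal) * normal
}

#' Russian roulette termination
#'
#' Unbiased low-weight termination: with probability `p_survive` the weight
#' is divided by `p_survive`, otherwise the photon terminates.
#'
#' @param w Photon weights below the roulette threshold.
#' @param p_survive Survival probability in (0, 1].
#' @param seed Optional integer seed (uses R's RNG).
#' @return Numeric vector of post-roulette weights (0 = terminated).
#' @export
roulette <- function(w, p_survive = 0.1, seed = NULL) {
  stopifnot(p_survive > 0, p_survive <= 1)
  if (!is.null(seed)) set.seed(seed)
  survived <- stats::runif(length(w)) < p_survive
  ifelse(survived, w / p_survive, 0)
}
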