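#' Construct a PPG trace
#'
#' @param time_s Uniformly sampled times (s).
#' @param value Intensity samples (arbitrary detector units).
#' @param wavelength_nm Wavelength tag (660 or 940).
#' @param meta Optional metadata list (e.g. generator ground truth).
#' @return An object of class `ppg_trace`.
#' @export
ppg_trace <- function(time_s, value, wavelength_nm = 660, meta = list()) {
  stopifnot(length(time_s) == length(value), length(time_s) >= 2)
  dt <- diff(time_s)
  if (max(abs(dt - dt[1])) > 1e-9) stop("sampling must be uniform")
  structure(list(time_s = time_s, value = value,
                 rate_hz = 1 / dt[1], wavelength_nm = wavelength_nm,
                 meta = meta),
            class = "ppg_trace")
}

#' @export
print.ppg_trace <- function(x, ...) {
  cat(sprintf("PPG trace: %g nm, %.1f s at %g Hz (%d samples)\n",
              x$wavelength_nm, diff(range(x$time_s)), x$rate_hz,
              length(x$value)))
  invisible(x)
}

#' Synthetic two-component PPG generator
#'
#' Emulates a measured PPG waveform: a cardiac oscillation (fundamental
#' plus a second harmonic, peak-normalized) riding on a dc level, plus an
#' optional slow baseline drift and wideband Gaussian noise.  The detected
#' intensity is `dc + ac * pulse(t)` with `pulse` in \[0, 1\], so the trough
#' level is exactly `dc` and the crest `dc + ac`, giving ground-truth
#' `PI = ac / dc` recorded in the trace metadata.
#'
#' @param duration_s Trace length (>= 10 s recommended).
#' @param rate_hz Sampling rate (default 25 Hz, one sample per LED frame).
#' @param heart_rate_hz Cardiac frequency; must lie in the 0.7--4 Hz band.
#' @param dc Trough (diastolic) intensity level.
#' @param pi Perfusion index; ac = pi * dc.
#' @param drift_amp Baseline drift amplitude (same units as `dc`).
#' @param drift_freq_hz Drift frequency (below the passband, e.g. 0.05 Hz).
#' @param noise_sd Gaussian noise standard deviation.
#' @param wavelength_nm Wavelength tag.
#' @param seed Integer seed (reproducible traces).
#' @return A [ppg_trace()] with `meta$dc_true`, `meta$ac_true`,
#'   `meta$pi_true`, `meta$heart_rate_hz`, `meta$noise_sd`.
#' @export
synth_ppg <- function(duration_s = 40, rate_hz = 25, heart_rate_hz = 1.2,
                      dc = 100, pi = 0.02, drift_amp = 0,
                      drift_freq_hz = 0.05, noise_sd = 0,
                      wavelength_nm = 660, seed = 1) {
  if (heart_rate_hz < 0.7 || heart_rate_hz > 4) {
    stop("heart rate must lie in the 0.7-4 Hz cardiac band")
  }
  # second harmonic must stay below Nyquist to avoid aliasing
  if (rate_hz <= 2 * (2 * heart_rate_hz)) {
    stop("sampling rate too low for the cardiac harmonics (aliasing)")
  }
  set.seed(seed)
  t <- seq(0, duration_s, by = 1 / rate_hz)
  raw_pulse <- cos(2 * base::pi * heart_rate_hz * t) +
    0.3 * cos(2 * base::pi * 2 * heart_rate_hz * t)
  pulse <- (raw_pulse - min(raw_pulse)) / diff(range(raw_pulse))
  ac <- pi * dc
  x <- dc + ac * pulse +
    drift_amp * sin(2 * base::pi * drift_freq_hz * t) +
    stats::rnorm(length(t), sd = noise_sd)
  ppg_trace(t, x, wavelength_nm = wavelength_nm,
            meta = list(dc_true = dc, ac_true = ac, pi_true = pi,
                        heart_rate_hz = heart_rate_hz,
                        drift_amp = drift_amp, noise_sd = noise_sd,
                        seed = seed))
}

#' Zero-phase cardiac-band filtering
#'
#' Order-4 Butterworth bandpass over the human cardiac band (default
#' 0.7--4 Hz), applied forward and backward (`signal::filtfilt`) so that
#' envelope peak positions are not shifted.  The dc offset is removed; the
#' trace mean is retained in the output metadata for envelope restoration.
#'
#' @param trace A [ppg_trace()].
#' @param low_hz,high_hz Band edges (Hz); sampling rate must exceed
#'   `2 * high_hz`.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return A filtered `ppg_trace` (zero-mean) with `meta$baseline` set.
#' @export
ppg_bandpass <- function(trace, low_hz = 0.7, high_hz = 4, order = 4) {
  fs <- trace$rate_hz
  if (fs <= 2 * high_hz) stop("sampling rate must exceed twice the band top")
  n <- length(trace$value)
  if (n < 3 * ceiling(fs / low_hz)) {
    stop("insufficient data: trace shorter than 3 filter lengths")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, trace$value - mean(trace$value))
  out <- trace
  out$value <- y
  out$meta$baseline <- mean(trace$value)
  out$meta$band_hz <- c(low_hz, high_hz)
  out
}

#' Envelope-based dc/ac extraction
#'
#' Finds local maxima and minima of the filtered trace (minimum peak
#' separation of a quarter cardiac period from the spectral heart-rate
#' estimate; prominence at least 10% of the interquartile range).  The dc
#' intensity is the mean of the bottom-envelope (local-minimum) levels of
#' the filtered signal restored to the raw baseline; the ac intensity is
#' the mean top-envelope level minus the dc.  Peaks within 2 s of the trace
#' edges are discarded (filter transients).
#'
#' @param filtered Output of [ppg_bandpass()] (carries the raw baseline).
#' @param raw The raw trace; used for the baseline if `filtered` lacks one.
#' @return An object of class `envelope_result`: `dc`, `ac`, peak indices.
#' @export
extract_envelopes <- function(filtered, raw = NULL) {
  x <- filtered$value
  fs <- filtered$rate_hz
  baseline <- filtered$meta$baseline %||%
    (if (!is.null(raw)) mean(raw$value) else 0)
  if (stats::sd(x) < 1e-12 * (abs(baseline) + 1)) {
    stop("flat signal: no cardiac oscillation found")
  }
  hr <- estimate_heart_rate(filtered)
  min_sep <- max(1L, round(0.25 * fs / hr))
  prom <- 0.1 * stats::IQR(x)
  find <- function(v) {
    pk <- pracma::findpeaks(v, minpeakdistance = min_sep,
                            minpeakheight = prom, sortstr = TRUE)
    if (is.null(pk)) integer(0) else sort(pk[, 2])
  }
  top_idx <- find(x)
  bot_idx <- find(-x)
  edge <- 2 * fs
  keep <- function(idx) idx[idx > edge & idx <= length(x) - edge]
  top_idx <- keep(top_idx); bot_idx <- keep(bot_idx)
  if (length(top_idx) < 3 || length(bot_idx) < 3) {
    stop("too few peaks: need at least 3 cardiac cycles")
  }
  # 3-point parabolic refinement: the sampled extremum undershoots the
  # true crest/trough at a 25 Hz rate
  refine <- function(idx) {
    vapply(idx, function(i) {
      a <- x[i - 1]; b <- x[i]; c <- x[i + 1]
      den <- a - 2 * b + c
      if (abs(den) < 1e-30) return(b)
      d <- 0.5 * (a - c) / den
      if (abs(d) > 1) return(b)
      b - 0.25 * (a - c) * d
    }, numeric(1))
  }
  dc <- baseline + mean(refine(bot_idx))
  ac <- (baseline + mean(refine(top_idx))) - dc
  structure(list(dc = dc, ac = ac, top_idx = top_idx, bot_idx = bot_idx,
                 heart_rate_hz = hr),
            class = "envelope_result")
}

#' @keywords internal
estimate_heart_rate <- function(trace, low_hz = 0.7, high_hz = 4) {
  x <- trace$value - mean(trace$value)
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]^2
  f <- (seq_len(floor(n / 2)) - 1) * trace$rate_hz / n
  band <- f >= low_hz & f <= high_hz
  if (!any(band)) stop("no spectral content in the cardiac band")
  f[band][which.max(sp[band])]
}

#' Band-ratio signal-to-noise estimate
#'
#' Welch mean periodogram (10-s Hann segments, 50% overlap, segment mean
#' removed) normalized so that band powers integrate the trace variance.
#' SNR_dB = 10 log10(power in 0.7--4 Hz / power in 7--10 Hz).
#'
#' @param trace A raw [ppg_trace()] at least 10 s long.
#' @param signal_band,noise_band Frequency bands (Hz).
#' @return An object of class `snr_result`: `signal_power`, `noise_power`,
#'   `snr_db` (`Inf` flagged if the noise band is empty of power).
#' @export
snr_db <- function(trace, signal_band = c(0.7, 4), noise_band = c(7, 10)) {
  if (diff(range(trace$time_s)) < 10) {
    stop("trace must be at least 10 s for 0.1 Hz frequency resolution")
  }
  psd <- welch_psd(trace$value, trace$rate_hz, seg_s = 10, overlap = 0.5)
  bp <- function(band) {
    sel <- psd$f >= band[1] & psd$f <= band[2]
    sum(psd$p[sel]) * psd$df
  }
  sp <- bp(signal_band); np <- bp(noise_band)
  db <- if (np <= 0) Inf else 10 * log10(sp / np)
  structure(list(signal_power = sp, noise_power = np, snr_db = db,
                 infinite = !is.finite(db)),
            class = "snr_result")
}

#' @keywords internal
welch_psd <- function(x, fs, seg_s = 10, overlap = 0.5) {
  nseg <- min(length(x), round(seg_s * fs))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * base::pi * (seq_len(nseg) - 1) / (nseg - 1))
  wnorm <- sum(w^2)
  nf <- floor(nseg / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))[seq_len(nf)]^2
  }
  df <- fs / nseg
  # one-sided PSD per Hz such that sum(p)*df ~ variance of x
  p <- acc / length(starts) / (wnorm * fs) * 2
  list(f = (seq_len(nf) - 1) * df, p = p, df = df)
}

#' Perfusion indices and R ratio from a two-wavelength trace pair
#'
#' Runs the full analysis chain (bandpass, envelope dc/ac, SNR) on the red
#' and NIR traces, forms PI per wavelength and R = PI_red / PI_nir, and
#' flags reliability: SNR >= 15 dB at both wavelengths and R strictly
#' inside the 0.5--0.7 window used for SpO2 > 95% screening.
#'
#' @param trace_red,trace_nir Raw [ppg_trace()] objects (660 and 940 nm).
#' @param snr_limit_db Minimum acceptable SNR (dB).
#' @param r_window Open reliability interval for R.
#' @return A list of class `ppg_report`: `pi_red`, `pi_nir`, `r`, per-trace
#'   dc/ac/SNR, and logical flags `snr_ok`, `r_ok`, `reliable`.
#' @export
pi_and_r <- function(trace_red, trace_nir, snr_limit_db = 15,
                     r_window = c(0.5, 0.7)) {
  one <- function(tr) {
    env <- extract_envelopes(ppg_bandpass(tr), tr)
    list(env = env, snr = snr_db(tr),
         pi = perfusion_index(env$ac, env$dc))
  }
  red <- one(trace_red); nir <- one(trace_nir)
  r <- r_ratio(red$pi, nir$pi)
  snr_ok <- red$snr$snr_db >= snr_limit_db && nir$snr$snr_db >= snr_limit_db
  r_ok <- r > r_window[1] && r < r_window[2]
  structure(list(
    pi_red = red$pi, pi_nir = nir$pi, r = r,
    dc_red = red$env$dc, ac_red = red$env$ac,
    dc_nir = nir$env$dc, ac_nir = nir$env$ac,
    snr_red_db = red$snr$snr_db, snr_nir_db = nir$snr$snr_db,
    snr_ok = snr_ok, r_ok = r_ok, reliable = snr_ok && r_ok
  ), class = "ppg_report")
}

#' @export
print.ppg_report <- function(x, ...) {
  cat(sprintf("PPG report: PI_red = %.4g, PI_nir = %.4g, R = %.4g\n",
              x$pi_red, x$pi_nir, x$r))
  cat(sprintf("  SNR: %.1f dB (red), %.1f dB (NIR); SNR ok: %s\n",
              x$snr_red_db, x$snr_nir_db, x$snr_ok))
  cat(sprintf("  R in (0.5, 0.7): %s; reliable: %s\n", x$r_ok, x$reliable))
  invisible(x)
}

#' Read / write PPG sample tables
#'
#' Comma-separated columns `time_s, value, wavelength_nm`; one file may
#' hold several wavelengths.
#'
#' @param path File path.
#' @return `read_ppg_csv`: a named list of [ppg_trace()] objects keyed by
#'   wavelength.
#' @export
read_ppg_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (nrow(tab) == 0) stop("empty input: no PPG samples in ", path)
  need <- c("time_s", "value", "wavelength_nm")
  if (!all(need %in% names(tab))) {
    stop("PPG table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(tab[need]))
  if (length(bad)) {
    stop("malformed rows (missing values) at lines: ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  out <- lapply(split(tab, tab$wavelength_nm), function(d) {
    ppg_trace(d$time_s, d$value, wavelength_nm = d$wavelength_nm[1])
  })
  names(out) <- vapply(out, function(t) as.character(t$wavelength_nm), "")
  out
}

#' @rdname read_ppg_csv
#' @param traces A `ppg_trace` or list of them.
#' @export
write_ppg_csv <- function(traces, path) {
  if (inherits(traces, "ppg_trace")) traces <- list(traces)
  tab <- do.call(rbind, lapply(traces, function(t) {
    data.frame(time_s = t$time_s, value = t$value,
               wavelength_nm = t$wavelength_nm)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
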