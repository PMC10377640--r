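test_that("synthetic generator: ground truth metadata and determinism", {
  a <- synth_ppg(seed = 11)
  b <- synth_ppg(seed = 11)
  expect_identical(a$value, b$value)
  expect_equal(a$meta$pi_true, a$meta$ac_true / a$meta$dc_true)
  # trough level is dc, crest is dc + ac (clean trace)
  expect_equal(min(a$value), a$meta$dc_true, tolerance = 1e-6)
  expect_equal(max(a$value), a$meta$dc_true + a$meta$ac_true,
               tolerance = 1e-6)
  expect_error(synth_ppg(heart_rate_hz = 0.3), "0.7-4")
  expect_error(synth_ppg(rate_hz = 4, heart_rate_hz = 1.2), "aliasing")
})

test_that("bandpass: passband identity, stopband rejection, zero phase", {
  t <- seq(0, 60, by = 1 / 25)
  mk <- function(x) ppg_trace(t, x)
  core <- function(x) {  # interior samples away from filtfilt edges
    sel <- t > 5 & t < 55
    x[sel]
  }
  # 1.2 Hz sinusoid passes with < 1% amplitude change
  s12 <- sin(2 * pi * 1.2 * t)
  f <- ppg_bandpass(mk(100 + s12))
  expect_equal(max(abs(core(f$value))), 1, tolerance = 0.01)
  # 0.05 Hz drift attenuated by >= 40 dB
  drift <- sin(2 * pi * 0.05 * t)
  fd <- ppg_bandpass(mk(100 + drift))
  expect_lt(max(abs(core(fd$value))), 0.01)
  # mixed 1.2 + 8 Hz: output tracks the cardiac component
  noisy <- s12 + sin(2 * pi * 8 * t)
  fn <- ppg_bandpass(mk(100 + noisy))
  expect_gt(cor(core(fn$value), core(s12)), 0.99)
  # zero-phase: peak positions unshifted by more than one sample
  raw_peaks <- which(diff(sign(diff(s12))) == -2) + 1
  filt_peaks <- which(diff(sign(diff(fn$value))) == -2) + 1
  near <- vapply(raw_peaks[raw_peaks > 125 & raw_peaks < 1375],
                 function(p) min(abs(filt_peaks - p)), numeric(1))
  expect_true(all(near <= 1))
  expect_error(ppg_bandpass(ppg_trace(t[1:50], rnorm(50))), "insufficient")
})

test_that("envelope extraction recovers generator dc and ac", {
  tr <- synth_ppg(duration_s = 40, dc = 100, pi = 0.05, seed = 3)
  env <- extract_envelopes(ppg_bandpass(tr), tr)
  expect_equal(env$dc, 100, tolerance = 0.02)
  expect_equal(env$ac, 5, tolerance = 0.05)
  # doubling the generator ac at fixed dc doubles the recovered ac
  tr2 <- synth_ppg(duration_s = 40, dc = 100, pi = 0.10, seed = 3)
  env2 <- extract_envelopes(ppg_bandpass(tr2), tr2)
  expect_equal(env2$ac / env$ac, 2, tolerance = 0.05)
  # constant trace: flat-signal error
  flat <- ppg_trace(tr$time_s, rep(100, length(tr$time_s)))
  expect_error(extract_envelopes(flat, flat), "flat|insufficient|peaks")
})

test_that("noiseless, driftless recovery is accurate to 0.5%", {
  tr <- synth_ppg(duration_s = 40, dc = 80, pi = 0.02,
                  drift_amp = 0, noise_sd = 0, seed = 5)
  env <- extract_envelopes(ppg_bandpass(tr), tr)
  expect_equal(env$ac / env$dc, 0.02, tolerance = 0.005)
})

test_that("strong sub-band drift leaves PI recovery within 10%", {
  tr <- synth_ppg(duration_s = 40, dc = 100, pi = 0.02,
                  drift_amp = 10 * 0.02 * 100, drift_freq_hz = 0.05,
                  noise_sd = 0, seed = 6)
  env <- extract_envelopes(ppg_bandpass(tr), tr)
  expect_equal(env$ac / env$dc, 0.02, tolerance = 0.1 * 0.02)
})

test_that("SNR estimator matches the analytic band-power construction", {
  fs <- 25; t <- seq(0, 60, by = 1 / fs)
  A <- 1; sigma <- 0.3
  # analytic: signal band power A^2/2; white-noise band power
  # sigma^2 * bandwidth / (fs/2)
  snr_true <- 10 * log10((A^2 / 2) / (sigma^2 * 3 / (fs / 2)))
  est <- vapply(1:50, function(k) {
    set.seed(k)
    x <- A * sin(2 * pi * 1.2 * t) + rnorm(length(t), sd = sigma)
    snr_db(ppg_trace(t, x + 100))$snr_db
  }, numeric(1))
  expect_lt(abs(mean(est) - snr_true), 1)
  # amplitude x10 at fixed noise adds 20 dB
  set.seed(1)
  n <- rnorm(length(t), sd = sigma)
  s1 <- snr_db(ppg_trace(t, A * sin(2 * pi * 1.2 * t) + n))$snr_db
  s2 <- snr_db(ppg_trace(t, 10 * A * sin(2 * pi * 1.2 * t) + n))$snr_db
  expect_equal(s2 - s1, 20, tolerance = 0.2)
  # a tone inside the noise band drives SNR negative
  s3 <- snr_db(ppg_trace(t, sin(2 * pi * 8 * t) + 0.01 * n))$snr_db
  expect_lt(s3, 0)
})

test_that("pi_and_r: ratio recovery and reliability flags", {
  red <- synth_ppg(duration_s = 40, dc = 100, pi = 0.0037,
                   wavelength_nm = 660, noise_sd = 0.02, seed = 21)
  nir <- synth_ppg(duration_s = 40, dc = 120, pi = 0.0059,
                   wavelength_nm = 940, noise_sd = 0.02, seed = 22)
  rep <- pi_and_r(red, nir)
  expect_equal(rep$r, 0.0037 / 0.0059, tolerance = 0.05)
  expect_true(rep$r_ok)        # ~0.627 inside the (0.5, 0.7) window
  expect_true(rep$snr_ok)
  # equal generator PIs give R = 1, outside the window
  a <- synth_ppg(duration_s = 40, pi = 0.02, wavelength_nm = 660, seed = 31)
  b <- synth_ppg(duration_s = 40, pi = 0.02, wavelength_nm = 940, seed = 32)
  rep2 <- pi_and_r(a, b)
  expect_equal(rep2$r, 1, tolerance = 0.02)
  expect_false(rep2$r_ok)
})

test_that("R-window boundary values are flagged unreliable (open interval)", {
  # exercise the flag rule directly around the quoted limits
  win <- c(0.5, 0.7)
  inside <- function(r) r > win[1] & r < win[2]
  expect_false(inside(0.5))
  expect_false(inside(0.7))
  expect_true(inside(0.6))
})

test_that("PI/R parameter recovery: median error < 5% over 100 seeded traces", {
  set.seed(123)
  n <- 100
  pis <- exp(runif(n, log(0.001), log(0.05)))
  snrs <- runif(n, 10, 40)
  fs <- 25
  err <- r_err <- numeric(n)
  for (k in seq_len(n)) {
    # calibrate the noise sd to the requested band-ratio SNR: the raw
    # two-harmonic pulse shape is rescaled by its peak-to-peak range, so
    # the fundamental has amplitude ac/range and the harmonic 0.3*ac/range
    ac <- 100 * pis[k]
    th <- seq(0, 2 * pi, length.out = 10001)
    rngpp <- diff(range(cos(th) + 0.3 * cos(2 * th)))
    sig_pow <- (ac / rngpp)^2 / 2 + (0.3 * ac / rngpp)^2 / 2
    sigma <- sqrt(sig_pow / 10^(snrs[k] / 10) * (fs / 2) / 3)
    tr <- synth_ppg(duration_s = 40, rate_hz = fs, dc = 100, pi = pis[k],
                    noise_sd = sigma, seed = 1000 + k)
    tr2 <- synth_ppg(duration_s = 40, rate_hz = fs, dc = 100,
                     pi = pis[k] * 1.2, noise_sd = sigma, seed = 2000 + k,
                     wavelength_nm = 940)
    env <- extract_envelopes(ppg_bandpass(tr), tr)
    env2 <- extract_envelopes(ppg_bandpass(tr2), tr2)
    err[k] <- abs(env$ac / env$dc - pis[k]) / pis[k]
    r_hat <- (env$ac / env$dc) / (env2$ac / env2$dc)
    r_err[k] <- abs(r_hat - 1 / 1.2) * 1.2
  }
  expect_lt(median(err), 0.05)
  expect_lt(median(r_err), 0.05)
})

test_that("trace CSV round trip and malformed input errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "tr.csv")
  tr <- list(synth_ppg(duration_s = 12, seed = 1),
             synth_ppg(duration_s = 12, seed = 2, wavelength_nm = 940))
  write_ppg_csv(tr, p)
  back <- read_ppg_csv(p)
  expect_setequal(names(back), c("660", "940"))
  expect_equal(back[["660"]]$value, tr[[1]]$value)
  # empty file
  p2 <- file.path(dir, "empty.csv")
  writeLines("time_s,value,wavelength_nm", p2)
  expect_error(read_ppg_csv(p2), "empty")
  # malformed rows reported with line numbers
  p3 <- file.path(dir, "bad.csv")
  writeLines(c("time_s,value,wavelength_nm", "0,1,660", "0.04,,660",
               "0.08,3,660"), p3)
  expect_error(read_ppg_csv(p3), "lines: 3")
})
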