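#!/usr/bin/env Rscript
# Optional long-run suite at the published problem sizes (hours on one
# CPU).  Reproduces, at full scale:
#   1. repetition statistics: 100 repeats x 1e7 photons at theta_PL = 25,
#      60, 90 deg (reference stds 0.0039 / 0.0356 / 0.1278 and 3-sigma
#      bands +/-1.17% / 10.68% / 38.34%);
#   2. the full 15-angle calibration sweep at SpO2 = 70-100% for both
#      surrounds, the calibration curve, reliability limits and the
#      theta_max ladder (reference: 35/45/65 deg for the absorbing
#      surround at 4e7/7e7/1e8 photons; 85 deg for the mirror at 1e8);
#   3. PI at theta_max for the mirror surround (reference 0.42 at 660 nm).
# Usage: Rscript scripts/longrun.R [--photons 1e7] [--repeats 100] [--out dir]

suppressMessages(library(rpoxim))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(photons = 1e7, repeats = 100, out = "longrun_results", seed = 1L)
i <- 1
while (i <= length(args)) {
  if (args[i] == "--photons") { opt$photons <- as.numeric(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--repeats") { opt$repeats <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
  else i <- i + 1
}
dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

message("1/3 repetition statistics (", opt$repeats, " x ", opt$photons,
        " photons per angle)")
for (th in c(25, 60, 90)) {
  rs <- repetition_statistics(theta_deg = th, n_photons = opt$photons,
                              n_repeats = opt$repeats,
                              base_seed = opt$seed)
  print(rs)
  utils::write.csv(
    data.frame(repeat_index = seq_along(rs$intensities),
               seed = rs$seeds, intensity = rs$intensities,
               normalized = rs$normalized),
    file.path(opt$out, sprintf("repeats_theta%02d.csv", th)),
    row.names = FALSE)
}

message("2/3 calibration sweeps (both surrounds, four SpO2 levels)")
sw <- angle_sweep(spo2 = c(0.70, 0.80, 0.90, 1.00), rho = c(0, 1),
                  n_photons = opt$photons, base_seed = opt$seed)
utils::write.csv(sw, file.path(opt$out, "calibration_sweep.csv"),
                 row.names = FALSE)
cal <- cmd_calibrate(sw, out_dir = opt$out)
print(cal$curve)
print(cal$limits)
cat("theta_max by surround:\n"); print(cal$theta_max)

message("3/3 PI at theta_max for the mirror surround")
tm <- cal$theta_max[["rho_1"]]
if (!is.na(tm)) {
  pr <- paired_run(theta_deg = tm, wavelength_nm = 660, rho = 1,
                   n_photons = opt$photons, seed = opt$seed)
  cat(sprintf("PI(660 nm) at theta_PL = %g deg (mirror): %.3f\n",
              tm, perfusion_index(pr)))
}
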