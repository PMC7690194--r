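#!/usr/bin/env Rscript
# Redox status: quantify NAD+/NADH from simulated cycling-assay plates
# sampled across one oscillation cycle, compute the NAD+/NADH ratio, and
# summarise the ORP probe channel with the same cycle statistics used for
# metabolites.

suppressPackageStartupMessages(library(chemosc))
dir.create("results", showWarnings = FALSE)

ts <- read_timeseries("results/datasets/oscillation.csv")
w <- post_transient_window(ts, 52)
cyc <- segment_cycles(ts_channel(w, "X"), w$time_h)

# emulate assay sampling: NAD+ tracks biomass, NADH stays low and flat
X <- ts_channel(w, "X")
nad_true <- 0.02 + 0.015 * (X - min(X)) / diff(range(X))
nadh_true <- rep(0.004, length(X))
plate_nad <- simulate_assay_plate(nad_true, slope_per_mM = 2,
                                  intercept = 0.01, noise_sd = 0.001,
                                  seed = 7)
plate_nadh <- simulate_assay_plate(nadh_true, slope_per_mM = 2,
                                   intercept = 0.01, noise_sd = 0.001,
                                   seed = 8)
cal <- fit_calibration(plate_nad$standards$conc_mM,
                       plate_nad$standards$slope)
message(sprintf("calibration: %.3f dA570/min/mM, R^2 = %.4f",
                cal$slope_per_mM, cal$r_squared))
nad <- quantify_samples(plate_nad$samples$slope, cal, analyte = "NAD+",
                        t = w$time_h)
nadh <- quantify_samples(plate_nadh$samples$slope, cal, analyte = "NADH",
                         t = w$time_h)
ratio <- nad_ratio(nad$concentration_mM, nadh$concentration_mM)
out <- data.frame(t = w$time_h, nad_mM = nad$concentration_mM,
                  nadh_mM = nadh$concentration_mM, ratio = ratio$ratio)
utils::write.csv(out, "results/redox_nad.csv", row.names = FALSE)

rs <- cycle_statistics(ratio$ratio, w$time_h, cyc)
message(sprintf(
  "NAD+/NADH ratio: %.1f at its cycle maximum (phase %.2f, oxidised stage I) down to %.1f",
  rs$mean_max, rs$mean_max_phase, rs$mean_min))

orp <- cycle_statistics(ts_channel(w, "ORP"), w$time_h, cyc)
message(sprintf(
  "ORP: max %.0f mV (phase %.2f), min %.0f mV (phase %.2f)",
  orp$mean_max, orp$mean_max_phase, orp$mean_min, orp$mean_min_phase))
utils::write.csv(orp$records, "results/redox_orp_cycles.csv",
                 row.names = FALSE)

# formate dehydrogenase: no detectable activity is encoded as a flat slope
fdh <- fdh_activity(0, protein_mg_per_mL = 4)
message("FDH specific activity (flat A340 slope): ",
        fdh$specific_U_per_mg, " U/mg")
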