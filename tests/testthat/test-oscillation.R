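test_that("a sinusoid yields one peak and one trough per period", {
  t <- seq(0, 255, by = 1)
  x <- 2 + sin(2 * pi * t / 51)
  ext <- detect_extrema(x, t)
  expect_equal(nrow(ext$peaks), 5)
  expect_equal(nrow(ext$troughs), 5)
  # analytic peak positions 12.75 + 51k, within grid spacing
  expect_equal(ext$peaks$t, 12.75 + 51 * (0:4), tolerance = 1)
  expect_equal(ext$troughs$t, 38.25 + 51 * (0:4), tolerance = 1)
  # alternation
  both <- sort(c(ext$peaks$t, ext$troughs$t))
  kinds <- ifelse(both %in% ext$peaks$t, "p", "t")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("constant and empty series are handled", {
  t <- 0:10
  ext <- detect_extrema(rep(3, 11), t)
  expect_equal(nrow(ext$peaks), 0)
  expect_equal(nrow(ext$troughs), 0)
  expect_error(detect_extrema(numeric(0), numeric(0)), "empty")
})

test_that("detected extrema match the brute-force windowed oracle", {
  cfg <- chemostat_preset("oscillation", noise_cv = 0.02, seed = 21)
  obs <- simulate_chemostat(cfg)$observed
  x <- ts_channel(obs, "X")
  t <- obs$time_h
  ext <- detect_extrema(x, t)
  oracle <- brute_extrema(x, t, w = 15)
  # every prominent detected peak is a window-best point of the oracle
  expect_true(all(ext$peaks$index %in% oracle$peaks))
  # one per simulated cycle: peaks at 20 + 52k inside the 0-290 h grid
  expect_equal(nrow(ext$peaks), 6)
})

test_that("period detection recovers a 51-h sinusoid", {
  t <- seq(0, 255, by = 1)
  p <- detect_period(2 + sin(2 * pi * t / 51), t)
  expect_equal(p$mean_period_h, 51, tolerance = 1)
  expect_false(p$acf_disagrees)
})

test_that("on dense noiseless data peak-to-peak intervals equal the period", {
  cfg <- chemostat_preset("oscillation", noise_cv = 0,
                          t_grid = seq(0, 260, by = 0.05))
  sim <- simulate_chemostat(cfg)
  p <- detect_period(ts_channel(sim$noise_free, "X"), cfg$t_grid,
                     refine = FALSE)
  expect_equal(p$periods_h, rep(52, length(p$periods_h)), tolerance = 0.05)
})

test_that("period estimate is invariant to positive affine transforms", {
  cfg <- chemostat_preset("oscillation", noise_cv = 0.02, seed = 9)
  obs <- simulate_chemostat(cfg)$observed
  x <- ts_channel(obs, "X")
  t <- obs$time_h
  p1 <- detect_period(x, t)
  p2 <- detect_period(3.7 * x + 11, t)
  expect_equal(p1$mean_period_h, p2$mean_period_h)
  expect_equal(p1$peak_times_h, p2$peak_times_h)
})

test_that("fewer than two peaks reports no period", {
  t <- 0:20
  p <- detect_period(2 + 0.001 * sin(2 * pi * t / 51), t)
  expect_true(is.na(p$mean_period_h))
  expect_equal(length(p$periods_h), 0L)
})

test_that("cycle segmentation splits a sinusoid into equal stages", {
  t <- seq(0, 255, by = 0.5)
  cyc <- segment_cycles(2 + sin(2 * pi * t / 51), t)
  expect_gte(nrow(cyc), 3)
  expect_equal(cyc$stage1_duration, rep(25.5, nrow(cyc)), tolerance = 1)
  expect_equal(cyc$stage2_duration, rep(25.5, nrow(cyc)), tolerance = 1)
  # durations sum exactly to the trough-to-trough interval by construction
  expect_equal(cyc$stage1_duration + cyc$stage2_duration, cyc$period)
})

test_that("the oscillatory preset shows the configured stage asymmetry", {
  cfg <- chemostat_preset("oscillation", noise_cv = 0,
                          t_grid = seq(0, 290, by = 0.5))
  sim <- simulate_chemostat(cfg)
  cyc <- segment_cycles(ts_channel(sim$noise_free, "X"), cfg$t_grid)
  expect_equal(mean(cyc$stage1_duration), 20, tolerance = 0.6)
  expect_equal(mean(cyc$stage2_duration), 32, tolerance = 0.6)
  expect_lt(mean(cyc$stage1_duration), mean(cyc$stage2_duration))
})

test_that("no complete cycle gives an empty table with a warning", {
  t <- seq(0, 30, by = 1)
  expect_warning(cyc <- segment_cycles(2 + sin(2 * pi * t / 51), t),
                 "no complete")
  expect_equal(nrow(cyc), 0)
})

test_that("cycle statistics report extrema, phases and stages", {
  cfg <- chemostat_preset("oscillation", noise_cv = 0,
                          t_grid = seq(0, 290, by = 0.5))
  sim <- simulate_chemostat(cfg)
  t <- cfg$t_grid
  X <- ts_channel(sim$noise_free, "X")
  cyc <- segment_cycles(X, t)
  # biomass peak phase equals stage1_duration / period by definition
  sx <- cycle_statistics(X, t, cyc)
  expect_equal(sx$mean_max_phase, mean(cyc$stage1_duration / cyc$period),
               tolerance = 1e-6)
  # H2 maximum sits mid stage II, minimum mid stage I
  sh <- cycle_statistics(ts_channel(sim$noise_free, "H2"), t, cyc)
  expect_true(all(sh$records$stage[sh$records$kind == "max"] == "II"))
  expect_true(all(sh$records$stage[sh$records$kind == "min"] == "I"))
  expect_equal(sh$mean_max, 2.47, tolerance = 0.01)
  expect_equal(sh$mean_min, 0.07, tolerance = 0.01)
  # constant channel: max = min = the constant
  cst <- cycle_statistics(rep(4, length(t)), t, cyc)
  expect_equal(cst$mean_max, 4)
  expect_equal(cst$mean_min, 4)
  expect_error(cycle_statistics(X, t, cyc[0, ]), "empty")
})

test_that("phase lags recover constructed shifts and configured offsets", {
  t <- seq(0, 255, by = 0.5)
  a <- 2 + sin(2 * pi * t / 52)
  cyc <- segment_cycles(a, t)
  expect_equal(phase_lag(a, a, t, cyc), 0)
  b <- 2 + sin(2 * pi * (t - 13) / 52)   # T/4 shift
  expect_equal(phase_lag(a, b, t, cyc), 13, tolerance = 0.6)
  expect_equal(phase_lag(b, a, t, cyc), -13, tolerance = 0.6)
  # preset: lactate lags 1,3-PDO by the configured 16 h
  cfg <- chemostat_preset("oscillation", noise_cv = 0,
                          t_grid = seq(0, 290, by = 0.5))
  sim <- simulate_chemostat(cfg)
  X <- ts_channel(sim$noise_free, "X")
  cycp <- segment_cycles(X, cfg$t_grid)
  lag <- phase_lag(ts_channel(sim$noise_free, "PDO"),
                   ts_channel(sim$noise_free, "lactate"), cfg$t_grid, cycp)
  expect_gt(lag, 0)
  expect_equal(lag, 16, tolerance = 1.6)
  expect_error(phase_lag(a, rep(1, length(t)), t, cyc), "oscillatory")
})

test_that("phase lags are additive modulo the period", {
  cfg <- chemostat_preset("oscillation", noise_cv = 0,
                          t_grid = seq(0, 290, by = 0.5))
  sim <- simulate_chemostat(cfg)
  t <- cfg$t_grid
  X <- ts_channel(sim$noise_free, "X")
  cyc <- segment_cycles(X, t)
  ab <- phase_lag(X, ts_channel(sim$noise_free, "lactate"), t, cyc)
  bc <- phase_lag(ts_channel(sim$noise_free, "lactate"),
                  ts_channel(sim$noise_free, "CO2"), t, cyc)
  ac <- phase_lag(X, ts_channel(sim$noise_free, "CO2"), t, cyc)
  diff_mod <- (ab + bc - ac) %% 52
  expect_lt(min(diff_mod, 52 - diff_mod), 1.5)
})

test_that("a bimodal M-shaped rate counts two peaks per cycle", {
  t <- seq(0, 260, by = 0.5)
  X <- 2 + sin(2 * pi * t / 52)
  cyc <- segment_cycles(X, t)
  # two humps per cycle, as the lactate production rate shows
  m <- 1 + 0.6 * sin(2 * pi * t / 26) + 0.2 * sin(2 * pi * t / 52)
  expect_equal(peaks_per_cycle(m, t, cyc), rep(2L, nrow(cyc)))
  # unimodal control aligned with the cycles
  expect_equal(peaks_per_cycle(X, t, cyc), rep(1L, nrow(cyc)))
  # brute-force dense-grid local-maxima count agrees
  oracle <- brute_extrema(m, t, w = 6)
  counts <- vapply(seq_len(nrow(cyc)), function(k) {
    sum(t[oracle$peaks] >= cyc$trough_start_t[k] &
          t[oracle$peaks] < cyc$trough_end_t[k])
  }, integer(1))
  expect_equal(peaks_per_cycle(m, t, cyc), counts)
})

test_that("regime classification separates sustained, damped and none", {
  t <- seq(0, 290, by = 3)
  expect_equal(classify_regime(rep(2, length(t)), t), "none")
  osc <- simulate_chemostat(chemostat_preset("oscillation"))$observed
  expect_equal(classify_regime(ts_channel(osc, "X"), osc$time_h),
               "sustained")
  dmp <- simulate_chemostat(chemostat_preset("damped"))$observed
  expect_equal(classify_regime(ts_channel(dmp, "X"), dmp$time_h), "damped")
  std <- simulate_chemostat(chemostat_preset("steady"))$observed
  expect_equal(classify_regime(ts_channel(std, "X"), std$time_h), "none")
})

test_that("the damping threshold flips labels at the half-life boundary", {
  # threshold: amplitude half-life <= 3 periods; T = 50 h
  t <- seq(0, 600, by = 1)
  T <- 50
  lam_crit <- log(2) / (3 * T)
  mk <- function(lam) sin(2 * pi * t / T) * exp(-lam * t)
  expect_equal(classify_regime(mk(lam_crit * 2), t), "damped")
  expect_equal(classify_regime(mk(lam_crit / 4), t), "sustained")
})

test_that("oscillation_summary composes regimes, periods and lags", {
  cfg <- chemostat_preset("oscillation", noise_cv = 0.02, seed = 42)
  obs <- simulate_chemostat(cfg)$observed
  s <- oscillation_summary(post_transient_window(obs, 52))
  expect_equal(s$regime, "sustained")
  expect_equal(s$mean_period_h, 52, tolerance = 2)
  expect_true(all(c("X", "H2", "ORP") %in% names(s$channels)))
  expect_gt(s$channels$lactate$lag_h, 5)
  std <- simulate_chemostat(chemostat_preset("steady"))$observed
  s2 <- oscillation_summary(std)
  expect_equal(s2$regime, "none")
  expect_length(s2$channels, 0)
})
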