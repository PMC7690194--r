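test_that("constant production reaches the closed-form steady state", {
  # mu = D, constant q_P, constant X: C_P -> q_P * X / D
  out <- integrate_balances(seq(0, 400, by = 5), c(X = 2, P = 0),
                            mu = 0.05, q_P = list(P = 0.3), D = 0.05)
  expect_equal(tail(out$P, 1), 0.3 * 2 / 0.05, tolerance = 1e-5)
  expect_equal(out$X, rep(2, nrow(out)), tolerance = 1e-8)
})

test_that("with all rates zero the substrate washes in along the closed form", {
  D <- 0.048; S_f <- 88
  out <- integrate_balances(seq(0, 60, by = 1), c(X = 1, substrate = 0),
                            mu = D, q_s = 0, D = D, S_f = S_f)
  expect_equal(out$substrate, S_f * (1 - exp(-D * out$time)),
               tolerance = 1e-6)
})

test_that("integration aborts when rates drive concentrations negative", {
  expect_error(
    integrate_balances(seq(0, 100, by = 1), c(X = 1, P = 0.5),
                       mu = 0.05, q_P = list(P = -0.5), D = 0.05),
    "negative")
})

test_that("noise-free simulation reproduces the configured waveforms", {
  sim <- osc_fine()
  cfg <- sim$config
  for (nm in names(cfg$waveforms)) {
    ana <- eval_waveform(cfg$waveforms[[nm]], cfg$t_grid,
                         ref_rise_fraction = cfg$waveforms$X$rise_fraction)
    scale <- max(diff(range(ana)), 1)
    expect_lt(max(abs(sim$noise_free$channels[[nm]] - ana)), 1e-4 * scale)
  }
})

test_that("noise-free output satisfies the balances to tolerance", {
  sim <- osc_fine()
  res <- balance_residual(sim$noise_free, sim$truth_rates)
  inner <- 3:(nrow(res) - 2)
  for (nm in names(res)[-1]) {
    scale <- max(diff(range(sim$noise_free$channels[[nm]])), 1)
    expect_lt(max(abs(res[[nm]][inner])), 1e-3 * scale)
  }
})

test_that("sustained cycles repeat: per-cycle peaks vary under 1% after transient", {
  sim <- osc_fine()
  t <- sim$config$t_grid
  for (nm in c("X", "PDO", "H2", "CO2")) {
    v <- sim$noise_free$channels[[nm]]
    peaks <- vapply(1:2, function(k) max(v[t >= k * 52 & t < (k + 1) * 52]),
                    numeric(1))
    expect_lt(abs(diff(peaks)) / mean(peaks), 0.01)
  }
})

test_that("configured lag structure shows up in the simulated channels", {
  sim <- osc_fine()
  t <- sim$config$t_grid
  win <- t >= 52 & t < 104   # one post-transient cycle
  peak_t <- function(nm) t[win][which.max(sim$noise_free$channels[[nm]][win])]
  # biomass and 1,3-PDO peak together; H2 peaks later; CO2 peaks earlier
  expect_equal(peak_t("PDO"), peak_t("X"), tolerance = 0.5)
  expect_equal(peak_t("H2") - peak_t("X"), 16, tolerance = 0.5)
  expect_equal(peak_t("X") - peak_t("CO2"), 10, tolerance = 0.5)
})

test_that("add_noise is a no-op at zero CV and reproducible from its seed", {
  ts <- make_sine_ts()
  expect_identical(add_noise(ts, 0, 1), ts)
  n1 <- add_noise(ts, 0.05, 123)
  n2 <- add_noise(ts, 0.05, 123)
  expect_identical(n1, n2)
  n3 <- add_noise(ts, 0.05, 124)
  expect_false(identical(n1$channels$X, n3$channels$X))
})

test_that("noise CV calibrates: replicate draws of one point match the target", {
  t <- c(0, 1, 2)
  ts <- timeseries_set(t, data.frame(X = c(10, 10, 10)), c(X = "g/L"),
                       kinds = c(X = "biomass"))
  draws <- vapply(seq_len(1e4), function(s) {
    add_noise(ts, 0.02, s)$channels$X[1]
  }, numeric(1))
  cv <- sd(draws) / mean(draws)
  expect_lt(abs(cv - 0.02) / 0.02, 0.1)
})

test_that("identical config and seed give identical datasets", {
  cfg <- chemostat_preset("oscillation", t_grid = seq(0, 120, by = 3),
                          noise_cv = 0.03, seed = 42)
  s1 <- simulate_chemostat(cfg)
  s2 <- simulate_chemostat(cfg)
  expect_identical(s1$observed$channels, s2$observed$channels)
  expect_identical(s1$truth_rates, s2$truth_rates)
})

test_that("presets load with their documented operating points", {
  osc <- chemostat_preset("oscillation")
  expect_equal(osc$D, 0.048)
  expect_equal(osc$S_f, 88)
  expect_equal(osc$waveforms$X$period_h, 52)
  damped <- chemostat_preset("damped")
  expect_equal(damped$S_f, 44)
  expect_gt(damped$damping_rate, 0)
  none <- chemostat_preset("no_oscillation")
  expect_equal(none$D, 0.096)
  expect_error(chemostat_preset("nonexistent"), "unknown preset")
})

test_that("perturbed initial products relax onto the configured cycle", {
  # product balances are exponentially stable at rate D given the biomass
  # trajectory, so zeroed products wash back onto the limit cycle
  cfg <- chemostat_preset("oscillation", noise_cv = 0,
                          t_grid = seq(0, 260, by = 1))
  on_cycle <- vapply(c("X", "glycerol", "PDO", "butyrate", "acetate",
                       "lactate", "formate", "H2", "CO2"), function(nm) {
    eval_waveform(cfg$waveforms[[nm]], 0,
                  ref_rise_fraction = cfg$waveforms$X$rise_fraction)
  }, numeric(1))
  names(on_cycle) <- c("X", "substrate", "PDO", "butyrate", "acetate",
                       "lactate", "formate", "H2", "CO2")
  st <- on_cycle
  st[-(1:2)] <- st[-(1:2)] * 1.2     # products displaced 20% off-cycle
  sim <- simulate_chemostat(cfg, state0 = st)
  ana <- eval_waveform(cfg$waveforms$PDO, cfg$t_grid,
                       ref_rise_fraction = cfg$waveforms$X$rise_fraction)
  late <- cfg$t_grid >= 208
  expect_lt(max(abs(sim$noise_free$channels$PDO[late] - ana[late])), 0.5)
})
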