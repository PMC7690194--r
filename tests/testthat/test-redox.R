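test_that("calibration on exact data returns the exact line", {
  conc <- seq(0.01, 0.05, by = 0.01)
  cal <- fit_calibration(conc, 2 * conc)
  expect_equal(cal$slope_per_mM, 2, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  # two points: exact interpolating line
  cal2 <- fit_calibration(c(0.01, 0.05), c(0.03, 0.11))
  expect_equal(cal2$slope_per_mM, 2, tolerance = 1e-10)
  expect_equal(cal2$intercept, 0.01, tolerance = 1e-10)
  expect_error(fit_calibration(c(0.02, 0.02), c(1, 2)), "distinct")
})

test_that("noisy calibration equals the closed-form least-squares solution", {
  set.seed(42)
  conc <- rep(seq(0.01, 0.05, by = 0.01), each = 3)
  slope <- 0.02 + 1.8 * conc + rnorm(length(conc), sd = 0.003)
  cal <- fit_calibration(conc, slope)
  # normal-equations oracle
  b_or <- cov(conc, slope) / var(conc)
  a_or <- mean(slope) - b_or * mean(conc)
  expect_equal(cal$slope_per_mM, b_or, tolerance = 1e-10)
  expect_equal(cal$intercept, a_or, tolerance = 1e-10)
})

test_that("quantification inverts the calibration with QC flags", {
  cal <- fit_calibration(seq(0.01, 0.05, by = 0.01),
                         0.01 + 2 * seq(0.01, 0.05, by = 0.01))
  # a standard's slope returns that standard's concentration
  q <- quantify_samples(0.01 + 2 * 0.03, cal, analyte = "NAD+")
  expect_equal(q$concentration_mM, 0.03, tolerance = 1e-10)
  # blank slope -> zero
  expect_equal(quantify_samples(cal$intercept, cal)$concentration_mM, 0)
  # below blank: clipped and flagged
  q2 <- quantify_samples(0.005, cal)
  expect_equal(q2$concentration_mM, 0)
  expect_match(q2$qc_flags, "below_blank")
  # far above top standard: flagged extrapolated
  q3 <- quantify_samples(0.01 + 2 * 0.2, cal)
  expect_match(q3$qc_flags, "extrapolated")
})

test_that("assay plate round-trip recovers concentrations within 5% at 1% noise", {
  true <- c(0.015, 0.025, 0.04)
  # noise sd = 1% of the top-standard slope
  plate <- simulate_assay_plate(true, slope_per_mM = 2, intercept = 0.01,
                                noise_sd = 0.01 * (0.01 + 2 * 0.05),
                                seed = 99)
  cal <- fit_calibration(plate$standards$conc_mM, plate$standards$slope)
  q <- quantify_samples(plate$samples$slope, cal)
  expect_lt(max(abs(q$concentration_mM - true) / true), 0.05)
  # noise-free plates make the round trip an identity
  p0 <- simulate_assay_plate(true, noise_sd = 0, seed = 1)
  cal0 <- fit_calibration(p0$standards$conc_mM, p0$standards$slope)
  q0 <- quantify_samples(p0$samples$slope, cal0)
  expect_equal(q0$concentration_mM, true, tolerance = 1e-9)
  # zero concentration gives the blank slope when noise-free
  pz <- simulate_assay_plate(0, intercept = 0.01, noise_sd = 0, seed = 1)
  expect_equal(pz$samples$slope, 0.01)
})

test_that("NAD+/NADH ratio masks vanishing NADH and scales covariantly", {
  r <- nad_ratio(c(0.04, 0.05), c(0.02, 0.0005))
  expect_equal(r$ratio[1], 2)
  expect_true(is.na(r$ratio[2]))
  expect_true(r$masked[2])
  r2 <- nad_ratio(3 * c(0.04, 0.05), c(0.02, 0.025))
  expect_equal(r2$ratio, 3 * nad_ratio(c(0.04, 0.05), c(0.02, 0.025))$ratio)
})

test_that("oscillatory NAD+ over flat NADH phase-locks the ratio to NAD+", {
  # constructed per the reported redox pattern: NAD+ oscillates with
  # biomass, NADH stays low and flat
  cfg <- chemostat_preset("oscillation", noise_cv = 0,
                          t_grid = seq(0, 290, by = 0.5))
  sim <- simulate_chemostat(cfg)
  t <- cfg$t_grid
  X <- ts_channel(sim$noise_free, "X")
  nad <- 0.02 + 0.01 * (X - min(X)) / diff(range(X))
  nadh <- rep(0.004, length(t))
  ratio <- nad_ratio(nad, nadh)$ratio
  cyc <- segment_cycles(X, t)
  expect_equal(phase_lag(nad, ratio, t, cyc), 0, tolerance = 0.6)
})

test_that("FDH activity converts absorbance slopes to units correctly", {
  # hand-checked: 0.0622 A/min over eps 6.22 /mM/cm, 1 cm, 1 mL assay
  # -> 0.01 mM/min -> 1e-5 mmol/min
  a <- fdh_activity(0.0622, protein_mg_per_mL = 5)
  expect_equal(a$nadh_mmol_per_min, 1e-5, tolerance = 1e-12)
  expect_equal(a$units_U, 1e-5, tolerance = 1e-12)
  expect_equal(a$specific_U_per_mg, 1e-5 / (5 * 0.2), tolerance = 1e-12)
  # zero slope -> zero activity; doubling the slope doubles activity
  expect_equal(fdh_activity(0, protein_mg_per_mL = 5)$units_U, 0)
  expect_equal(fdh_activity(0.1244, protein_mg_per_mL = 5)$units_U,
               2 * a$units_U)
  expect_error(fdh_activity(0.1, protein_mg_per_mL = 5,
                            assay_volume_mL = 0), "positive")
})

test_that("plate files read with roles split and blanks zeroed", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "well,role,analyte,conc_mM,slope",
    "A1,standard,NAD+,0.01,0.031",
    "A2,standard,NAD+,0.05,0.110",
    "A3,blank,NAD+,,0.009",
    "B1,sample,NAD+,,0.065"), path)
  plate <- read_plate(path)
  expect_equal(nrow(plate$standards), 3)
  expect_equal(plate$standards$conc_mM[3], 0)
  expect_equal(nrow(plate$samples), 1)
  bad <- tempfile()
  writeLines("well,role", bad)
  expect_error(read_plate(bad), "missing column")
})
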