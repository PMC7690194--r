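#' Fit a linear calibration curve for the enzymatic cycling assay
#'
#' The NAD+/NADH cycling assay reads out a rate of absorbance increase at
#' 570 nm; concentrations are obtained by calibrating that slope against a
#' series of standards (0.01-0.05 mM in the study). Ordinary least squares
#' of slope on concentration; the intercept is retained because the assay
#' carries a reagent blank.
#'
#' @param conc_mM standard concentrations, mM (>= 2 distinct values)
#' @param slope observed assay slopes, dA570/min
#' @return object of class `calibration_curve`: `slope_per_mM`,
#'   `intercept`, `r_squared`, `standards`
#' @export
fit_calibration <- function(conc_mM, slope) {
  stopifnot(length(conc_mM) == length(slope), length(conc_mM) >= 2L)
  if (length(unique(conc_mM)) < 2L) {
    stop("calibration needs at least 2 distinct concentrations")
  }
  fit <- stats::lm(slope ~ conc_mM)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((slope - mean(slope))^2)
  structure(
    list(slope_per_mM = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         standards = data.frame(conc_mM = conc_mM, slope = slope)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve: slope = %.4g /mM, intercept = %.4g, R^2 = %.4f (%d standards)\n",
    x$slope_per_mM, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Quantify sample concentrations from assay slopes
#'
#' Inverts the calibration: `conc = (slope - intercept) / slope_per_mM`.
#' Concentrations that come out negative after blank correction are clipped
#' to 0 and flagged `below_blank`; slopes implying more than 1.5x the top
#' standard are flagged `extrapolated`.
#'
#' @param sample_slopes observed slopes, dA570/min
#' @param curve a [fit_calibration()] result
#' @param analyte label (`"NAD+"` or `"NADH"`), recorded in the output
#' @param t optional sampling times, hours
#' @return data.frame: `analyte`, `t`, `slope`, `concentration_mM`,
#'   `qc_flags`
#' @export
quantify_samples <- function(sample_slopes, curve, analyte = NA_character_,
                             t = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope_per_mM <= 0) {
    stop("invalid assay: calibration slope must be positive")
  }
  conc <- (sample_slopes - curve$intercept) / curve$slope_per_mM
  top <- max(curve$standards$conc_mM)
  flags <- character(length(conc))
  neg <- conc < 0
  flags[neg] <- "below_blank"
  conc[neg] <- 0
  extra <- conc > 1.5 * top
  flags[extra] <- trimws(paste(flags[extra], "extrapolated"))
  data.frame(analyte = analyte,
             t = if (is.null(t)) NA_real_ else t,
             slope = sample_slopes, concentration_mM = conc,
             qc_flags = flags)
}

#' NAD+/NADH ratio series
#'
#' Elementwise ratio of matched NAD+ and NADH series; the ratio tracks the
#' cell's redox state (oxidised in the growth rising stage, reduced in the
#' falling stage). NADH values at or below `floor_mM` give a masked (`NA`)
#' ratio rather than an unstable division.
#'
#' @param nad_mM NAD+ concentrations, mM
#' @param nadh_mM NADH concentrations, mM (same length)
#' @param floor_mM masking floor for NADH (default 1e-3 mM)
#' @return data.frame: `ratio`, `masked`
#' @export
nad_ratio <- function(nad_mM, nadh_mM, floor_mM = 1e-3) {
  stopifnot(length(nad_mM) == length(nadh_mM))
  masked <- !is.finite(nadh_mM) | nadh_mM <= floor_mM
  ratio <- ifelse(masked, NA_real_, nad_mM / nadh_mM)
  data.frame(ratio = ratio, masked = masked)
}

#' Formate dehydrogenase activity from an absorbance slope
#'
#' Converts the rate of NADH appearance at 340 nm into enzyme units. The
#' NADH formation rate in the cuvette is
#' `dA340/dt / (extinction * path) * assay_volume`; one unit is the amount
#' of enzyme producing 1 mmol NADH per minute (the study's unit
#' definition), and specific activity normalises to the protein contained
#' in the assayed extract volume.
#'
#' @param dA340_per_min absorbance slope at 340 nm, 1/min (>= 0)
#' @param protein_mg_per_mL extract protein concentration, mg/mL
#' @param extinction_mM_cm NADH molar extinction coefficient,
#'   1/(mM cm); 6.22 by default (not reported in the study; configurable)
#' @param path_cm cuvette path length, cm
#' @param assay_volume_mL reaction volume, mL
#' @param extract_volume_mL volume of cell-free extract added, mL
#' @return list: `nadh_mmol_per_min`, `units_U` (mmol/min), and
#'   `specific_U_per_mg`
#' @export
fdh_activity <- function(dA340_per_min, protein_mg_per_mL,
                         extinction_mM_cm = 6.22, path_cm = 1,
                         assay_volume_mL = 1, extract_volume_mL = 0.2) {
  stopifnot(dA340_per_min >= 0, extinction_mM_cm > 0, path_cm > 0)
  if (assay_volume_mL <= 0 || extract_volume_mL <= 0 ||
      protein_mg_per_mL <= 0) {
    stop("volumes and protein concentration must be positive")
  }
  rate_mM_per_min <- dA340_per_min / (extinction_mM_cm * path_cm)
  nadh_mmol_per_min <- rate_mM_per_min * assay_volume_mL / 1000
  protein_mg <- protein_mg_per_mL * extract_volume_mL
  list(nadh_mmol_per_min = nadh_mmol_per_min,
       units_U = nadh_mmol_per_min,
       specific_U_per_mg = nadh_mmol_per_min / protein_mg)
}

#' Simulate an enzymatic-cycling assay plate
#'
#' Generates standard and sample wells whose slopes are linear in
#' concentration plus Gaussian noise: the synthetic counterpart of the
#' cycling-assay calibration, used for round-trip recovery tests. The
#' standard series spans 0.01-0.05 mM as in the study protocol.
#'
#' @param true_conc_mM true sample concentrations, mM
#' @param slope_per_mM true calibration slope, dA570/min/mM
#' @param intercept true blank slope, dA570/min
#' @param noise_sd Gaussian noise sd on every slope, dA570/min
#' @param seed integer seed
#' @param standards_mM standard concentrations (default
#'   `seq(0.01, 0.05, by = 0.01)`)
#' @return list: `standards` (conc_mM, slope), `samples` (true_conc_mM,
#'   slope)
#' @export
simulate_assay_plate <- function(true_conc_mM, slope_per_mM = 2,
                                 intercept = 0.01, noise_sd = 0,
                                 seed = 1L,
                                 standards_mM = seq(0.01, 0.05, by = 0.01)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  std_slope <- intercept + slope_per_mM * standards_mM +
    stats::rnorm(length(standards_mM), sd = noise_sd)
  smp_slope <- intercept + slope_per_mM * true_conc_mM +
    stats::rnorm(length(true_conc_mM), sd = noise_sd)
  list(standards = data.frame(conc_mM = standards_mM, slope = std_slope),
       samples = data.frame(true_conc_mM = true_conc_mM, slope = smp_slope))
}

#' Read a delimited assay-plate file
#'
#' Columns: `well, role(standard|sample|blank), analyte, conc_mM, slope`.
#' Standards carry their known concentration; blanks are treated as 0 mM
#' standards.
#'
#' @param path CSV file path
#' @return list of data.frames: `standards`, `samples`
#' @export
read_plate <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "analyte", "conc_mM", "slope")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("plate file missing column(s): ",
                         paste(miss, collapse = ", "))
  d$conc_mM[d$role == "blank"] <- 0
  list(standards = d[d$role %in% c("standard", "blank"), ],
       samples = d[d$role == "sample", ])
}
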