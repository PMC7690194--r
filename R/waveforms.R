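#' Asymmetric periodic waveform specification
#'
#' Describes one channel of a limit-cycle chemostat oscillation as a smooth
#' periodic wave: a rising flank occupying `rise_fraction` of the period and
#' a falling flank occupying the remainder, scaled between `level_min` and
#' `level_max`. The flanks are quintic Hermite segments with zero slope and
#' matched curvature at both extrema, so the waveform is C2-smooth across the
#' whole cycle while keeping sharp, localizable peaks and troughs and
#' plateau-like shoulders on the slow flank.
#'
#' `phase_offset_h` places this channel's peak relative to the reference
#' (biomass) peak; positive values peak later in the cycle, matching the
#' lagged lactate/formate/H2 channels of the fermentation, negative values
#' lead (CO2).
#'
#' @param period_h cycle period in hours (> 0)
#' @param rise_fraction fraction of the cycle spent rising, in (0, 1)
#' @param phase_offset_h offset of this channel's peak relative to the
#'   reference peak, hours (positive = later)
#' @param level_min,level_max channel levels at trough and peak, in the
#'   channel's own units; `level_max >= level_min`; equal values give a
#'   constant channel
#' @return an object of class `waveform`
#' @examples
#' w <- waveform(52, 20 / 52, 0, 0.4, 3.6)
#' eval_waveform(w, c(0, 20, 52))  # trough, peak, trough
#' @export
waveform <- function(period_h, rise_fraction, phase_offset_h = 0,
                     level_min = 0, level_max = 1) {
  stopifnot(is.numeric(period_h), length(period_h) == 1L, is.finite(period_h),
            period_h > 0)
  stopifnot(is.numeric(rise_fraction), length(rise_fraction) == 1L,
            rise_fraction > 0, rise_fraction < 1)
  stopifnot(is.numeric(phase_offset_h), length(phase_offset_h) == 1L,
            is.finite(phase_offset_h))
  stopifnot(is.numeric(level_min), is.numeric(level_max),
            is.finite(level_min), is.finite(level_max),
            level_max >= level_min)
  structure(
    list(period_h = period_h, rise_fraction = rise_fraction,
         phase_offset_h = phase_offset_h,
         level_min = level_min, level_max = level_max),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "waveform: T = %g h, rise %.1f h / fall %.1f h, levels [%g, %g], peak offset %+g h\n",
    x$period_h, x$rise_fraction * x$period_h,
    (1 - x$rise_fraction) * x$period_h,
    x$level_min, x$level_max, x$phase_offset_h))
  invisible(x)
}

# Quintic Hermite segment on x in [0, 1] with value v0 -> v1, zero end
# slopes, and prescribed end second derivatives s0, s1 (in x units).
# Returns value (deriv = 0), first (1) or second (2) derivative w.r.t. x.
.quintic <- function(x, v0, v1, s0, s1, deriv = 0L) {
  # Hermite basis for (value0, value1, sec0, sec1); slopes fixed at 0.
  if (deriv == 0L) {
    h1 <- 10 * x^3 - 15 * x^4 + 6 * x^5
    b0 <- (x^2 - 3 * x^3 + 3 * x^4 - x^5) / 2
    b1 <- (x^3 - 2 * x^4 + x^5) / 2
    v0 + (v1 - v0) * h1 + s0 * b0 + s1 * b1
  } else if (deriv == 1L) {
    h1 <- 30 * x^2 - 60 * x^3 + 30 * x^4
    b0 <- (2 * x - 9 * x^2 + 12 * x^3 - 5 * x^4) / 2
    b1 <- (3 * x^2 - 8 * x^3 + 5 * x^4) / 2
    (v1 - v0) * h1 + s0 * b0 + s1 * b1
  } else {
    h1 <- 60 * x - 180 * x^2 + 120 * x^3
    b0 <- (2 - 18 * x + 36 * x^2 - 20 * x^3) / 2
    b1 <- (6 * x - 24 * x^2 + 20 * x^3) / 2
    (v1 - v0) * h1 + s0 * b0 + s1 * b1
  }
}

# Unit cycle template u(phi) on phi in [0, 1): trough 0 at phi = 0, peak 1
# at phi = r, back to 0 at phi = 1. C2-periodic: curvature at trough and at
# peak is the same approached from either flank (kappa = pi^2 / (2 * r_h *
# f_h) in phase-squared units scaled per flank), which is what lets
# finite-difference derivative estimators stay clean through the extremes.
.unit_cycle <- function(phi, r, deriv = 0L) {
  kappa <- pi^2 / (2 * r * (1 - r))  # shared extremum curvature, phi units
  out <- numeric(length(phi))
  up <- phi < r
  if (any(up)) {
    x <- phi[up] / r
    val <- .quintic(x, 0, 1, kappa * r^2, -kappa * r^2, deriv = deriv)
    out[up] <- val / r^deriv
  }
  if (any(!up)) {
    x <- (phi[!up] - r) / (1 - r)
    val <- .quintic(x, 1, 0, -kappa * (1 - r)^2, kappa * (1 - r)^2,
                    deriv = deriv)
    out[!up] <- val / (1 - r)^deriv
  }
  out
}

#' Evaluate a periodic channel waveform
#'
#' Evaluates the waveform (or its time derivative) at times `t`, optionally
#' applying an exponential damping envelope to the oscillatory component so
#' the channel decays toward its midline, emulating oscillations that damp
#' out rather than sustain.
#'
#' The reference cycle starts (biomass trough) at `t_start`; the reference
#' peak then sits at `t_start + ref_rise_fraction * period_h`, and this
#' channel peaks `phase_offset_h` hours after that.
#'
#' @param w a [waveform()]
#' @param t times in hours (finite)
#' @param damping_rate amplitude decay rate in 1/h, >= 0; 0 keeps the
#'   oscillation sustained
#' @param t_start time of the reference cycle start (reference-channel
#'   trough), hours
#' @param ref_rise_fraction rise fraction of the reference (biomass)
#'   channel, used to anchor `phase_offset_h`; defaults to this waveform's
#'   own rise fraction
#' @param deriv 0 for the value, 1 for the time derivative d/dt
#' @return numeric vector, channel units (or units/h for `deriv = 1`)
#' @export
eval_waveform <- function(w, t, damping_rate = 0, t_start = 0,
                          ref_rise_fraction = w$rise_fraction, deriv = 0L) {
  stopifnot(inherits(w, "waveform"))
  if (!all(is.finite(t))) stop("non-finite time values in 't'")
  stopifnot(damping_rate >= 0)
  mid <- (w$level_min + w$level_max) / 2
  amp <- w$level_max - w$level_min
  if (amp == 0) {
    return(if (deriv == 0L) rep(mid, length(t)) else rep(0, length(t)))
  }
  T <- w$period_h
  # this channel's peak time, then shift so u peaks (phi = r) there
  t_peak <- t_start + ref_rise_fraction * T + w$phase_offset_h
  phi <- ((t - t_peak) / T + w$rise_fraction) %% 1
  env <- exp(-damping_rate * (t - t_start))
  if (deriv == 0L) {
    mid + amp * env * (.unit_cycle(phi, w$rise_fraction) - 0.5)
  } else {
    du <- .unit_cycle(phi, w$rise_fraction, deriv = 1L) / T
    u0 <- .unit_cycle(phi, w$rise_fraction) - 0.5
    amp * env * (du - damping_rate * u0)
  }
}
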