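#' Detect prominent peaks and troughs of an oscillating channel
#'
#' Finds strict local maxima and minima, enforces peak/trough alternation,
#' and discards extrema whose excursion relative to their alternating
#' neighbours is below `prominence_frac` of the channel range. Ties between
#' equal-height neighbouring candidates resolve to the earliest time.
#'
#' @param x channel values
#' @param t times, hours (same length, strictly increasing)
#' @param prominence_frac minimum prominence as a fraction of the channel
#'   range (default 0.2)
#' @return list with data.frames `peaks` and `troughs`, columns `index`,
#'   `t`, `value`
#' @export
detect_extrema <- function(x, t, prominence_frac = 0.2) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  stopifnot(length(t) == n)
  rng <- diff(range(x, na.rm = TRUE))
  empty <- data.frame(index = integer(0), t = numeric(0), value = numeric(0))
  if (!is.finite(rng) || rng == 0) {
    return(list(peaks = empty, troughs = empty))
  }
  thr <- prominence_frac * rng
  # strict-left / non-strict-right comparison: plateaus keep earliest point
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                x[2:(n - 1)] >= x[3:n], FALSE)
  is_min <- c(FALSE, x[2:(n - 1)] < x[1:(n - 2)] &
                x[2:(n - 1)] <= x[3:n], FALSE)
  idx <- which(is_max | is_min)
  kind <- ifelse(is_max[idx], "max", "min")
  if (!length(idx)) return(list(peaks = empty, troughs = empty))
  # enforce alternation: among consecutive same-kind runs keep the most
  # extreme (earliest on ties)
  keep <- rep(TRUE, length(idx))
  repeat {
    ii <- which(keep)
    if (length(ii) < 2L) break
    same <- which(kind[ii[-length(ii)]] == kind[ii[-1]])
    if (!length(same)) break
    s <- same[1]
    a <- ii[s]; b <- ii[s + 1]
    va <- x[idx[a]]; vb <- x[idx[b]]
    drop <- if (kind[a] == "max") {
      if (vb > va) a else b          # earliest wins ties
    } else {
      if (vb < va) a else b
    }
    keep[drop] <- FALSE
  }
  idx <- idx[keep]; kind <- kind[keep]
  # prune low-prominence alternating pairs until all excursions >= thr
  repeat {
    if (length(idx) < 2L) break
    exc <- abs(diff(x[idx]))
    small <- which(exc < thr)
    if (!length(small)) break
    s <- small[which.min(exc[small])]
    # removing the adjacent pair (s, s+1) preserves alternation
    drop <- s:(s + 1L)
    idx <- idx[-drop]; kind <- kind[-drop]
  }
  mk <- function(k) {
    sel <- kind == k
    data.frame(index = idx[sel], t = t[idx[sel]], value = x[idx[sel]])
  }
  list(peaks = mk("max"), troughs = mk("min"))
}

# parabolic refinement of a grid extremum time from its two neighbours
.refine_time <- function(x, t, i) {
  if (i <= 1L || i >= length(x)) return(t[i])
  y0 <- x[i - 1L]; y1 <- x[i]; y2 <- x[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * 1e3) return(t[i])
  # local uniform-spacing approximation; clamp to one grid step
  h <- (t[i + 1L] - t[i - 1L]) / 2
  delta <- 0.5 * (y0 - y2) / denom
  t[i] + h * max(-1, min(1, delta))
}

#' Oscillation period from peak-to-peak intervals
#'
#' Per-cycle periods are the intervals between consecutive prominent peaks
#' (parabolically refined off-grid by default); the mean period averages
#' them after flagging cycles whose interval deviates more than
#' `outlier_frac` from the running median (the study's own period excludes
#' a stretch of irregular cycles). The estimate is cross-checked against
#' the lag of the first autocorrelation maximum; disagreement beyond 20%
#' sets `acf_disagrees` and raises a warning.
#'
#' @param x channel values
#' @param t times, hours
#' @param prominence_frac passed to [detect_extrema()]
#' @param refine parabolic sub-grid refinement of peak times (default TRUE)
#' @param outlier_frac relative deviation from the running median beyond
#'   which a cycle is excluded from the mean (default 0.3)
#' @return list: `mean_period_h`, `periods_h`, `peak_times_h`,
#'   `excluded` (logical per interval), `acf_period_h`, `acf_disagrees`,
#'   `n_peaks`
#' @export
detect_period <- function(x, t, prominence_frac = 0.2, refine = TRUE,
                          outlier_frac = 0.3) {
  ext <- detect_extrema(x, t, prominence_frac)
  pk <- ext$peaks
  if (nrow(pk) < 2L) {
    return(list(mean_period_h = NA_real_, periods_h = numeric(0),
                peak_times_h = pk$t, excluded = logical(0),
                acf_period_h = NA_real_, acf_disagrees = FALSE,
                n_peaks = nrow(pk)))
  }
  pt <- if (refine) vapply(pk$index, function(i) .refine_time(x, t, i),
                           numeric(1)) else pk$t
  periods <- diff(pt)
  run_med <- vapply(seq_along(periods), function(i) {
    stats::median(periods[seq_len(i)])
  }, numeric(1))
  excluded <- abs(periods - run_med) > outlier_frac * run_med
  mean_period <- mean(periods[!excluded])
  acf_period <- .acf_period(x, t)
  disagrees <- is.finite(acf_period) &&
    abs(acf_period - mean_period) > 0.2 * mean_period
  if (disagrees) {
    warning(sprintf(
      "peak-to-peak period (%.1f h) and autocorrelation period (%.1f h) disagree by > 20%%",
      mean_period, acf_period))
  }
  list(mean_period_h = mean_period, periods_h = periods, peak_times_h = pt,
       excluded = excluded, acf_period_h = acf_period,
       acf_disagrees = isTRUE(disagrees), n_peaks = nrow(pk))
}

# autocorrelation first-maximum period (series interpolated to a uniform
# grid when sampling is irregular)
.acf_period <- function(x, t) {
  n <- length(x)
  if (n < 8L) return(NA_real_)
  dt <- stats::median(diff(t))
  tu <- seq(t[1], t[n], by = dt)
  xu <- stats::approx(t, x, xout = tu)$y
  a <- stats::acf(xu, lag.max = length(xu) - 2L, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  # first local max after the initial decay
  for (k in 2:(length(a) - 1L)) {
    if (a[k] > a[k - 1L] && a[k] >= a[k + 1L] && a[k] > 0) {
      return((k - 1L) * dt)
    }
  }
  NA_real_
}

#' Segment biomass cycles into rising and falling stages
#'
#' Cycles are defined on the biomass channel as trough-peak-trough
#' triplets: stage I (growth rising stage) runs trough to peak, stage II
#' (falling stage) peak to trough; their durations sum exactly to the
#' trough-to-trough cycle length.
#'
#' @param X biomass values
#' @param t times, hours
#' @param prominence_frac passed to [detect_extrema()]
#' @return data.frame with one row per complete cycle: `cycle_index`,
#'   `trough_start_t`, `peak_t`, `trough_end_t`, `stage1_duration`,
#'   `stage2_duration`, `period`; zero rows (with a warning) when no
#'   complete cycle exists
#' @export
segment_cycles <- function(X, t, prominence_frac = 0.2) {
  ext <- detect_extrema(X, t, prominence_frac)
  tr <- ext$troughs$t
  pk <- ext$peaks$t
  rows <- list()
  if (length(tr) >= 2L) {
    for (k in seq_len(length(tr) - 1L)) {
      inside <- pk[pk > tr[k] & pk < tr[k + 1L]]
      if (!length(inside)) next
      peak_t <- inside[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        cycle_index = length(rows) + 1L,
        trough_start_t = tr[k], peak_t = peak_t, trough_end_t = tr[k + 1L],
        stage1_duration = peak_t - tr[k],
        stage2_duration = tr[k + 1L] - peak_t,
        period = tr[k + 1L] - tr[k])
    }
  }
  if (!length(rows)) {
    warning("no complete trough-peak-trough cycle found")
    return(data.frame(cycle_index = integer(0), trough_start_t = numeric(0),
                      peak_t = numeric(0), trough_end_t = numeric(0),
                      stage1_duration = numeric(0),
                      stage2_duration = numeric(0), period = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Per-cycle extrema and phase positions of a channel
#'
#' For each biomass-defined cycle, records the channel's maximum and
#' minimum (grid values), their times, and their phase positions in
#' `[0, 1)` measured from the stage-I trough, the stage boundary sitting at
#' `stage1_duration / period`. Aggregates mean and sd across cycles.
#'
#' @param x channel values
#' @param t times, hours
#' @param cycles cycle table from [segment_cycles()]
#' @return list: `records` (one row per cycle and extremum kind, with
#'   `stage` = `"I"`/`"II"`), `mean_max`, `sd_max`, `mean_min`, `sd_min`,
#'   `mean_max_phase`, `mean_min_phase`
#' @export
cycle_statistics <- function(x, t, cycles) {
  if (!nrow(cycles)) stop("empty cycle table")
  stopifnot(length(x) == length(t))
  recs <- list()
  for (k in seq_len(nrow(cycles))) {
    cy <- cycles[k, ]
    sel <- which(t >= cy$trough_start_t & t < cy$trough_end_t)
    if (length(sel) < 2L) next
    boundary <- cy$stage1_duration / cy$period
    for (kind in c("max", "min")) {
      i <- sel[if (kind == "max") which.max(x[sel]) else which.min(x[sel])]
      phase <- (t[i] - cy$trough_start_t) / cy$period
      recs[[length(recs) + 1L]] <- data.frame(
        cycle_index = cy$cycle_index, kind = kind, value = x[i], t = t[i],
        phase_position = phase,
        stage = if (phase < boundary) "I" else "II")
    }
  }
  records <- do.call(rbind, recs)
  mx <- records[records$kind == "max", ]
  mn <- records[records$kind == "min", ]
  list(records = records,
       mean_max = mean(mx$value), sd_max = stats::sd(mx$value),
       mean_min = mean(mn$value), sd_min = stats::sd(mn$value),
       mean_max_phase = mean(mx$phase_position),
       mean_min_phase = mean(mn$phase_position))
}

#' Phase lag between two oscillating channels
#'
#' Circular mean of the per-cycle peak-time differences of channel `b`
#' relative to channel `a`, folded into `(-T/2, T/2]` where `T` is the mean
#' cycle period. Positive lags mean `b` peaks later (lactate, formate and
#' H2 relative to biomass/1,3-PDO); the relation is antisymmetric modulo
#' `T`.
#'
#' @param a,b channel values on the common grid
#' @param t times, hours
#' @param cycles cycle table from [segment_cycles()]
#' @return lag in hours
#' @export
phase_lag <- function(a, b, t, cycles) {
  if (!nrow(cycles)) stop("empty cycle table")
  for (v in list(a, b)) {
    if (nrow(detect_extrema(v, t)$peaks) < 2L) {
      stop("channel is not oscillatory over the analysis window")
    }
  }
  T <- mean(cycles$period)
  diffs <- numeric(0)
  for (k in seq_len(nrow(cycles))) {
    cy <- cycles[k, ]
    sel <- which(t >= cy$trough_start_t & t < cy$trough_end_t)
    if (length(sel) < 2L) next
    ia <- sel[which.max(a[sel])]
    # b's peak searched in a full period centred on a's peak so lagged
    # channels straddling the cycle boundary are handled
    selb <- which(t >= t[ia] - T / 2 & t <= t[ia] + T / 2)
    ib <- selb[which.max(b[selb])]
    d <- (t[ib] - t[ia]) %% T
    if (d > T / 2) d <- d - T
    diffs <- c(diffs, d)
  }
  ang <- 2 * pi * diffs / T
  lag <- atan2(mean(sin(ang)), mean(cos(ang))) * T / (2 * pi)
  if (lag <= -T / 2) lag <- lag + T
  lag
}

#' Count prominent peaks of a series within each cycle
#'
#' Used for rate waveforms with multimodal cycles (the lactate production
#' rate shows an "M" shape with two peaks per oscillation cycle).
#'
#' @param x series values (e.g. a specific rate)
#' @param t times, hours
#' @param cycles cycle table from [segment_cycles()] (biomass-defined)
#' @param prominence_frac passed to [detect_extrema()]
#' @return integer vector, one count per cycle
#' @export
peaks_per_cycle <- function(x, t, cycles, prominence_frac = 0.2) {
  if (!nrow(cycles)) stop("empty cycle table")
  ok <- is.finite(x)
  ext <- detect_extrema(x[ok], t[ok], prominence_frac)
  vapply(seq_len(nrow(cycles)), function(k) {
    cy <- cycles[k, ]
    sum(ext$peaks$t >= cy$trough_start_t & ext$peaks$t < cy$trough_end_t)
  }, integer(1))
}

#' Classify the oscillation regime of a channel
#'
#' `"none"` when fewer than two prominent peaks exist; otherwise the log of
#' the peak amplitude (peak minus series median) is regressed on peak time
#' and the fitted decay is converted to an amplitude half-life. Regimes
#' whose amplitude halves within `halflife_periods` mean periods are
#' `"damped"`; the rest are `"sustained"`. The study's damped runs lose
#' their oscillation within a few cycles, which this threshold encodes; no
#' quantitative criterion is reported, so the half-life rule is this
#' package's own.
#'
#' @param x channel values
#' @param t times, hours
#' A relative-amplitude floor guards against measurement noise on a flat
#' channel being read as oscillation: series whose total range stays below
#' `min_amplitude_frac` of the median level are `"none"` outright (levels
#' near zero, e.g. a zero-mean sinusoid, are unaffected).
#'
#' @param prominence_frac passed to [detect_extrema()]
#' @param halflife_periods damping threshold in units of the mean period
#'   (default 3)
#' @param min_amplitude_frac minimum channel range as a fraction of the
#'   absolute median level (default 0.2)
#' @return one of `"sustained"`, `"damped"`, `"none"`
#' @export
classify_regime <- function(x, t, prominence_frac = 0.2,
                            halflife_periods = 3,
                            min_amplitude_frac = 0.2) {
  rng <- diff(range(x, na.rm = TRUE))
  if (!is.finite(rng) ||
      rng <= min_amplitude_frac * abs(stats::median(x, na.rm = TRUE))) {
    return("none")
  }
  ext <- detect_extrema(x, t, prominence_frac)
  if (nrow(ext$peaks) < 2L) return("none")
  per <- detect_period(x, t, prominence_frac)
  T <- per$mean_period_h
  amp <- ext$peaks$value - stats::median(x)
  ok <- amp > 0
  if (sum(ok) < 2L) return("none")
  fit <- stats::lm(log(amp[ok]) ~ ext$peaks$t[ok])
  decay <- -unname(stats::coef(fit)[2L])
  if (!is.finite(decay) || decay <= 0) return("sustained")
  halflife <- log(2) / decay
  if (is.finite(T) && halflife <= halflife_periods * T) "damped" else "sustained"
}

#' Full oscillation summary of a multichannel time series
#'
#' Segments cycles on the reference biomass channel, classifies its regime,
#' and reports per-channel period, per-cycle extrema with phase positions,
#' and phase lags relative to the reference.
#'
#' @param ts a [timeseries_set()]
#' @param ref_channel reference channel for cycle segmentation (default the
#'   biomass channel tag)
#' @param prominence_frac passed to the extremum detector
#' @return list of class `oscillation_summary`: `regime`, `reference`,
#'   `mean_period_h`, `cycles`, and per-channel `stats` / `lag_h`
#' @export
oscillation_summary <- function(ts, ref_channel = NULL,
                                prominence_frac = 0.2) {
  stopifnot(inherits(ts, "timeseries_set"))
  if (is.null(ref_channel)) {
    bio <- names(ts$kinds)[ts$kinds == "biomass"]
    ref_channel <- if (length(bio)) bio[1] else names(ts$channels)[1]
  }
  X <- ts_channel(ts, ref_channel)
  t <- ts$time_h
  regime <- classify_regime(X, t, prominence_frac)
  if (regime == "none") {
    out <- list(regime = regime, reference = ref_channel,
                mean_period_h = NA_real_, period = NULL, cycles = NULL,
                channels = list())
    class(out) <- "oscillation_summary"
    return(out)
  }
  per <- detect_period(X, t, prominence_frac)
  out <- list(regime = regime, reference = ref_channel,
              mean_period_h = per$mean_period_h, period = per,
              cycles = NULL, channels = list())
  cycles <- segment_cycles(X, t, prominence_frac)
  out$cycles <- cycles
  if (nrow(cycles)) {
    for (nm in names(ts$channels)) {
      x <- ts$channels[[nm]]
      st <- cycle_statistics(x, t, cycles)
      lag <- tryCatch(
        if (nm == ref_channel) 0 else phase_lag(X, x, t, cycles),
        error = function(e) NA_real_)
      out$channels[[nm]] <- list(stats = st, lag_h = lag)
    }
  }
  class(out) <- "oscillation_summary"
  out
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat(sprintf("oscillation_summary: regime '%s' (reference %s)\n",
              x$regime, x$reference))
  if (is.finite(x$mean_period_h)) {
    cat(sprintf("  mean period %.1f h over %d cycle(s)\n",
                x$mean_period_h, if (is.null(x$cycles)) 0L else nrow(x$cycles)))
  }
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-9s max %8.3f +/- %.3f  min %8.3f +/- %.3f  lag %+.1f h\n",
                nm, ch$stats$mean_max, ch$stats$sd_max,
                ch$stats$mean_min, ch$stats$sd_min, ch$lag_h))
  }
  invisible(x)
}
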