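# shared fixtures, all built in code

# simple sinusoidal timeseries_set around a positive offset
make_sine_ts <- function(period = 51, t_max = 5 * period, by = 1,
                         amplitude = 1, offset = 2) {
  t <- seq(0, t_max, by = by)
  x <- offset + amplitude * sin(2 * pi * t / period)
  timeseries_set(t, data.frame(X = x), c(X = "g/L"), D = 0.048,
                 kinds = c(X = "biomass"))
}

# brute-force extremum oracle: grid point that is the arg-max (arg-min) of
# the series over a centred window of half-width w hours
brute_extrema <- function(x, t, w) {
  peaks <- troughs <- integer(0)
  for (i in seq_along(x)) {
    sel <- which(t >= t[i] - w & t <= t[i] + w)
    if (length(sel) < 3L) next
    if (x[i] == max(x[sel]) && i == sel[which.max(x[sel])] &&
        x[i] > min(x[sel])) {
      peaks <- c(peaks, i)
    }
    if (x[i] == min(x[sel]) && i == sel[which.min(x[sel])] &&
        x[i] < max(x[sel])) {
      troughs <- c(troughs, i)
    }
  }
  list(peaks = peaks, troughs = troughs)
}

# brute-force N50: scan descending-sorted lengths for the first whose
# cumulative sum reaches half the total
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(as.numeric(s))
  run <- 0
  for (L in s) {
    run <- run + L
    if (run >= tot / 2) return(L)
  }
}

# oscillatory preset simulated once per run and reused (noise-free, fine grid)
osc_fine <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- chemostat_preset("oscillation", noise_cv = 0,
                              t_grid = seq(0, 156, by = 0.25))
      cache <<- simulate_chemostat(cfg)
    }
    cache
  }
})
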