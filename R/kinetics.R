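#' Local-polynomial derivative estimation on a (possibly irregular) grid
#'
#' Estimates dy/dt at every grid point by fitting a least-squares polynomial
#' of the given degree over a moving window of the nearest `window` samples
#' in *time* (not index), then differentiating the fit at the centre point.
#' On a uniform grid with `window = 3`, `degree = 2` this reduces exactly to
#' central differences (one-sided quadratic stencils at the ends). This is
#' the noise-robust Savitzky-Golay-type scheme the mass-balance rate
#' calculations require; the fermentation study leaves the differentiation
#' scheme unspecified.
#'
#' @param values numeric series
#' @param t_grid times, hours, strictly increasing, length >= 3
#' @param window odd window size >= 3 (samples)
#' @param degree local polynomial degree (default 2); must be < `window`
#' @return numeric vector of derivatives on the same grid
#' @export
estimate_derivative <- function(values, t_grid, window = 5L, degree = 2L) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 points to estimate a derivative")
  stopifnot(length(t_grid) == n, !is.unsorted(t_grid, strictly = TRUE))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  window <- min(window, n - (1L - n %% 2L))  # shrink for short series, keep odd
  degree <- min(as.integer(degree), window - 1L)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - window + 1L))
    idx <- lo:(lo + window - 1L)
    tt <- t_grid[idx] - t_grid[i]
    A <- outer(tt, 0:degree, `^`)
    coef <- qr.coef(qr(A), values[idx])
    out[i] <- coef[2L]
  }
  out
}

.mask_low_biomass <- function(q, X, x_min) {
  low <- !is.finite(X) | X <= x_min
  if (any(low)) {
    warning(sprintf("%d point(s) masked: biomass at or below %g g/L",
                    sum(low), x_min))
    q[low] <- NA_real_
  }
  q
}

#' Specific growth rate from the biomass balance
#'
#' `mu = (1/X) dX/dt + D`: at steady state (constant X) the growth rate
#' equals the dilution rate exactly. Points with biomass at or below
#' `x_min` are masked (`NA`) with a warning, since dividing by a vanishing
#' biomass is meaningless.
#'
#' @param X biomass concentrations, g/L
#' @param t_grid times, hours
#' @param D dilution rate, 1/h
#' @param x_min masking threshold for X, g/L
#' @param window,degree passed to [estimate_derivative()]
#' @return mu in 1/h on the grid
#' @export
specific_growth_rate <- function(X, t_grid, D, x_min = 1e-3,
                                 window = 5L, degree = 2L) {
  dX <- estimate_derivative(X, t_grid, window, degree)
  .mask_low_biomass(dX / X + D, X, x_min)
}

#' Specific glycerol uptake rate from the substrate balance
#'
#' Implements the dimensionally consistent substrate balance
#' `q_s = (1/X) (D S_f - D C_S - dC_S/dt)`, in g glycerol per g biomass per
#' hour. (The study's printed formula carries a `(dX/dt) C_S` term whose
#' units, g^2/(L^2 h), cannot be added to the feed term `D S_f`; it is read
#' here as a typographical slip for `D C_S`, which restores the standard
#' chemostat balance.) At steady state with complete consumption
#' (`C_S = 0`) this gives `q_s = D S_f / X`.
#'
#' @param C_S residual substrate concentrations, g/L
#' @param X biomass concentrations, g/L
#' @param t_grid times, hours
#' @param D dilution rate, 1/h
#' @param S_f feed concentration, g/L
#' @inheritParams specific_growth_rate
#' @return q_s in g/(g h) on the grid
#' @export
specific_substrate_uptake <- function(C_S, X, t_grid, D, S_f, x_min = 1e-3,
                                      window = 5L, degree = 2L) {
  dC <- estimate_derivative(C_S, t_grid, window, degree)
  .mask_low_biomass((D * S_f - D * C_S - dC) / X, X, x_min)
}

#' Specific production rate of a liquid product
#'
#' `q_P = (1/X) (dC_P/dt + D C_P)`; at steady state `q_P = D C_P / X`.
#'
#' @param C_P product concentrations, g/L
#' @inheritParams specific_substrate_uptake
#' @return q_P in g/(g h) on the grid
#' @export
specific_product_rate <- function(C_P, X, t_grid, D, x_min = 1e-3,
                                  window = 5L, degree = 2L) {
  dC <- estimate_derivative(C_P, t_grid, window, degree)
  .mask_low_biomass((dC + D * C_P) / X, X, x_min)
}

#' Specific production rate of a dissolved gas
#'
#' `q_gas = (1/X) (dC_gas/dt + D_G C_gas)` with the gas-phase dilution rate
#' `D_G` in place of `D`; units mmol/(g h).
#'
#' @param C_gas gas concentrations, mmol/L
#' @param D_G gas-phase dilution rate, 1/h
#' @inheritParams specific_substrate_uptake
#' @return q_gas in mmol/(g h) on the grid
#' @export
specific_gas_rate <- function(C_gas, X, t_grid, D_G, x_min = 1e-3,
                              window = 5L, degree = 2L) {
  dC <- estimate_derivative(C_gas, t_grid, window, degree)
  .mask_low_biomass((dC + D_G * C_gas) / X, X, x_min)
}

#' All specific rates of a time series
#'
#' Applies the four balance equations to every balanced channel of a
#' [timeseries_set()] (using its channel kinds and operating parameters)
#' and returns them on the same grid.
#'
#' @param ts a [timeseries_set()] with a biomass channel
#' @inheritParams specific_growth_rate
#' @return a `rate_profile` data.frame: `time_h`, `mu`, `q_<channel>` per
#'   balanced channel
#' @export
rate_profile <- function(ts, x_min = 1e-3, window = 5L, degree = 2L) {
  stopifnot(inherits(ts, "timeseries_set"))
  bio <- names(ts$kinds)[ts$kinds == "biomass"]
  if (length(bio) != 1L) stop("need exactly one biomass channel")
  X <- ts$channels[[bio]]
  t <- ts$time_h
  D <- ts$meta$D
  out <- data.frame(
    time_h = t,
    mu = specific_growth_rate(X, t, D, x_min, window, degree))
  for (nm in names(ts$channels)) {
    kind <- ts$kinds[[nm]]
    if (kind %in% c("biomass", "direct")) next
    v <- ts$channels[[nm]]
    out[[paste0("q_", nm)]] <- switch(kind,
      substrate = specific_substrate_uptake(v, X, t, D, ts$meta$S_f,
                                            x_min, window, degree),
      product   = specific_product_rate(v, X, t, D, x_min, window, degree),
      gas       = specific_gas_rate(v, X, t, ts$meta$D_G, x_min, window,
                                    degree))
  }
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' Mass-balance residuals of a rate profile (quality control)
#'
#' Re-inserts the rates into the chemostat balances and reports, per
#' balanced channel, `residual = d(channel)/dt - balance RHS`. Near zero
#' for self-consistent data; systematic structure flags either inconsistent
#' rates or measurement artefacts.
#'
#' @param ts a [timeseries_set()]
#' @param rates a `rate_profile` on the same grid (e.g. from
#'   [rate_profile()] or [truth_rates()])
#' @param window,degree derivative settings for the residual evaluation
#' @return data.frame of residual series, one column per balanced channel
#' @export
balance_residual <- function(ts, rates, window = 3L, degree = 2L) {
  stopifnot(inherits(ts, "timeseries_set"))
  if (!isTRUE(all.equal(ts$time_h, rates$time_h))) {
    stop("time grids of the series and the rate profile differ")
  }
  bio <- names(ts$kinds)[ts$kinds == "biomass"]
  X <- ts$channels[[bio]]
  t <- ts$time_h
  D <- ts$meta$D
  out <- data.frame(time_h = t)
  dX <- estimate_derivative(X, t, window, degree)
  out[[bio]] <- dX - (rates$mu - D) * X
  for (nm in names(ts$channels)) {
    kind <- ts$kinds[[nm]]
    if (kind %in% c("biomass", "direct")) next
    v <- ts$channels[[nm]]
    dv <- estimate_derivative(v, t, window, degree)
    q <- rates[[paste0("q_", nm)]]
    out[[nm]] <- switch(kind,
      substrate = dv - (D * (ts$meta$S_f - v) - q * X),
      product   = dv - (q * X - D * v),
      gas       = dv - (q * X - ts$meta$D_G * v))
  }
  out
}
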