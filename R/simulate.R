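#' Synthetic chemostat generator configuration
#'
#' Bundles the operating point, sampling grid and per-channel waveform
#' specifications that define a synthetic continuous-fermentation dataset.
#' Channels are parametrized at the *concentration* level (the quantity the
#' analyses observe); the matching specific-rate ground truth is derived
#' analytically from the chemostat balances by [truth_rates()], so the
#' generated data are mass-balance consistent by construction:
#'
#' \deqn{dX/dt = (\mu - D) X}
#' \deqn{dC_S/dt = D (S_f - C_S) - q_s X}
#' \deqn{dC_P/dt = q_P X - D C_P}
#' \deqn{dC_{gas}/dt = q_{gas} X - D_G C_{gas}}
#'
#' Channels tagged `"direct"` (e.g. the ORP probe signal) carry no balance
#' and no rate.
#'
#' @param D dilution rate, 1/h (> 0)
#' @param D_G gas-phase dilution rate, 1/h; required if any gas channel is
#'   present (the study never states it, so it is always explicit here)
#' @param S_f substrate feed concentration, g/L (> 0)
#' @param t_grid sampling times, hours, strictly increasing
#' @param waveforms named list of [waveform()] objects, one per channel;
#'   must contain the reference biomass channel
#' @param kinds named character vector: `"biomass"`, `"substrate"`,
#'   `"product"`, `"gas"` or `"direct"` per channel
#' @param units named character vector of channel units
#' @param damping_rate amplitude decay rate, 1/h (0 = sustained limit cycle)
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise (dimensionless, >= 0)
#' @param seed integer RNG seed for the noise draw
#' @param ref_channel name of the biomass reference channel
#' @return object of class `generator_config`
#' @export
generator_config <- function(D, D_G, S_f, t_grid, waveforms, kinds, units,
                             damping_rate = 0, noise_cv = 0, seed = 1L,
                             ref_channel = "X") {
  stopifnot(is.numeric(D), D > 0, is.numeric(S_f), S_f > 0)
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing")
  }
  stopifnot(noise_cv >= 0, damping_rate >= 0)
  stopifnot(is.list(waveforms), !is.null(names(waveforms)))
  lapply(waveforms, function(w) stopifnot(inherits(w, "waveform")))
  if (!ref_channel %in% names(waveforms)) {
    stop("reference channel '", ref_channel, "' missing from waveforms")
  }
  kinds <- kinds[names(waveforms)]
  units <- units[names(waveforms)]
  if (anyNA(kinds) || anyNA(units)) stop("kinds/units must cover every channel")
  if (any(kinds == "gas") && (!is.numeric(D_G) || !is.finite(D_G) || D_G <= 0)) {
    stop("D_G must be supplied (> 0) when gas channels are present")
  }
  structure(
    list(D = D, D_G = D_G, S_f = S_f, t_grid = t_grid,
         waveforms = waveforms, kinds = kinds, units = units,
         damping_rate = damping_rate, noise_cv = noise_cv,
         seed = as.integer(seed), ref_channel = ref_channel),
    class = "generator_config"
  )
}

# Analytic channel value / time-derivative for one configured channel.
.config_channel <- function(config, name, t, deriv = 0L) {
  w <- config$waveforms[[name]]
  ref <- config$waveforms[[config$ref_channel]]
  eval_waveform(w, t, damping_rate = config$damping_rate,
                t_start = config$t_grid[1],
                ref_rise_fraction = ref$rise_fraction, deriv = deriv)
}

#' Analytic ground-truth specific rates for a generator configuration
#'
#' Inverts the chemostat balances at the configured concentration waveforms:
#' `mu = D + X'/X`, `q_s = (D (S_f - C_S) - C_S') / X`,
#' `q_P = (C_P' + D C_P) / X`, `q_gas = (C_gas' + D_G C_gas) / X`.
#' These are the exact rates that, fed back through the balances, reproduce
#' the configured concentrations: the generator's retained truth.
#'
#' @param config a [generator_config()]
#' @param t times at which to evaluate (defaults to the config grid)
#' @return object of class `rate_profile`: data.frame with `time_h`, `mu`
#'   and one `q_<channel>` column per balanced channel
#' @export
truth_rates <- function(config, t = config$t_grid) {
  X <- .config_channel(config, config$ref_channel, t)
  dX <- .config_channel(config, config$ref_channel, t, deriv = 1L)
  out <- data.frame(time_h = t, mu = config$D + dX / X)
  for (nm in names(config$waveforms)) {
    kind <- config$kinds[[nm]]
    if (kind %in% c("biomass", "direct")) next
    C <- .config_channel(config, nm, t)
    dC <- .config_channel(config, nm, t, deriv = 1L)
    q <- switch(kind,
      substrate = (config$D * (config$S_f - C) - dC) / X,
      product   = (dC + config$D * C) / X,
      gas       = (dC + config$D_G * C) / X)
    out[[paste0("q_", nm)]] <- q
  }
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' Integrate the chemostat balances for given rate forcings
#'
#' Low-level ODE core: integrates biomass, substrate, product and gas
#' balances for arbitrary time-dependent specific-rate functions with an
#' adaptive integrator (`deSolve`, relative tolerance 1e-8), sampling the
#' dense solution onto `t_grid`.
#'
#' @param t_grid output times, hours
#' @param state0 named initial state (must include `X`)
#' @param mu,q_s specific growth rate and substrate uptake: functions of t
#'   (or single numbers, recycled); `q_s` may be `NULL` if no substrate
#'   channel is present
#' @param q_P named list of product-rate functions/constants (g/(g h))
#' @param q_gas named list of gas-rate functions/constants (mmol/(g h))
#' @param D,D_G,S_f operating parameters
#' @param neg_tol concentrations more negative than `-neg_tol * max(scale)`
#'   abort with an error: the configured rates must keep the state
#'   physical
#' @return data.frame of the state on `t_grid`
#' @export
integrate_balances <- function(t_grid, state0, mu, q_s = NULL,
                               q_P = list(), q_gas = list(),
                               D, D_G = NA_real_, S_f = NA_real_,
                               neg_tol = 1e-6) {
  as_fun <- function(f) if (is.function(f)) f else function(t) rep_len(f, length(t))
  mu <- as_fun(mu)
  if (!is.null(q_s)) q_s <- as_fun(q_s)
  q_P <- lapply(q_P, as_fun)
  q_gas <- lapply(q_gas, as_fun)
  nm_state <- names(state0)
  deriv <- function(t, y, parms) {
    X <- y[["X"]]
    dy <- numeric(length(y))
    names(dy) <- nm_state
    dy[["X"]] <- (mu(t) - D) * X
    if ("substrate" %in% nm_state) {
      dy[["substrate"]] <- D * (S_f - y[["substrate"]]) - q_s(t) * X
    }
    for (p in names(q_P)) dy[[p]] <- q_P[[p]](t) * X - D * y[[p]]
    for (g in names(q_gas)) dy[[g]] <- q_gas[[g]](t) * X - D_G * y[[g]]
    list(dy)
  }
  sol <- deSolve::ode(y = state0, times = t_grid, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  sol <- as.data.frame(sol)
  scale <- max(abs(state0), 1)
  if (min(as.matrix(sol[nm_state])) < -neg_tol * scale) {
    stop("integration produced negative concentrations beyond tolerance; ",
         "the configured rates must keep the state non-negative")
  }
  sol
}

#' Simulate a synthetic chemostat dataset
#'
#' Builds the analytic rate forcings from the configured concentration
#' waveforms, integrates the chemostat balances through `deSolve` from the
#' on-cycle initial state, and returns noisy observations together with the
#' noise-free solution and the exact rate truth. With `noise_cv = 0` the
#' observed series is the deterministic ODE solution. The first simulated
#' cycle is conventionally treated as transient by downstream recovery
#' statistics (see [post_transient_window()]).
#'
#' @param config a [generator_config()]
#' @param state0 optional named initial state; defaults to the configured
#'   waveform values at the first grid point (on-cycle start). Supplying
#'   e.g. `c(X = 0.1, substrate = S_f, ...)` gives a batch-start transient.
#' @return object of class `simulated_dataset`: list with `observed`
#'   (noisy [timeseries_set()]), `noise_free`, `truth_rates`
#'   ([truth_rates()] on the same grid) and `config`
#' @export
simulate_chemostat <- function(config, state0 = NULL) {
  stopifnot(inherits(config, "generator_config"))
  t_grid <- config$t_grid
  nms <- names(config$waveforms)
  kinds <- config$kinds
  balanced <- nms[kinds != "direct"]
  rates <- truth_rates(config, t_grid)

  # closures for the ODE forcing, analytic in t
  ref <- config$ref_channel
  mu_f <- function(t) {
    config$D + .config_channel(config, ref, t, 1L) /
      .config_channel(config, ref, t, 0L)
  }
  q_fun <- function(nm) {
    kind <- kinds[[nm]]
    force(nm)
    function(t) {
      X <- .config_channel(config, ref, t)
      C <- .config_channel(config, nm, t)
      dC <- .config_channel(config, nm, t, 1L)
      switch(kind,
        substrate = (config$D * (config$S_f - C) - dC) / X,
        product   = (dC + config$D * C) / X,
        gas       = (dC + config$D_G * C) / X)
    }
  }
  subs <- nms[kinds == "substrate"]
  prods <- nms[kinds == "product"]
  gases <- nms[kinds == "gas"]
  if (length(subs) > 1L) stop("at most one substrate channel supported")

  if (is.null(state0)) {
    state0 <- vapply(balanced, function(nm) .config_channel(config, nm, t_grid[1]),
                     numeric(1))
    names(state0) <- balanced
    names(state0)[balanced == ref] <- "X"
    if (length(subs)) names(state0)[balanced == subs] <- "substrate"
  }
  qs_f <- if (length(subs)) q_fun(subs) else NULL
  sol <- integrate_balances(
    t_grid, state0, mu = mu_f, q_s = qs_f,
    q_P = stats::setNames(lapply(prods, q_fun), prods),
    q_gas = stats::setNames(lapply(gases, q_fun), gases),
    D = config$D, D_G = config$D_G, S_f = config$S_f)

  channels <- data.frame(row.names = seq_along(t_grid))
  for (nm in nms) {
    channels[[nm]] <- if (kinds[[nm]] == "direct") {
      .config_channel(config, nm, t_grid)
    } else if (kinds[[nm]] == "biomass") {
      sol[["X"]]
    } else if (kinds[[nm]] == "substrate") {
      pmax(sol[["substrate"]], 0)
    } else {
      pmax(sol[[nm]], 0)
    }
  }
  clean <- timeseries_set(t_grid, channels, config$units,
                          D = config$D, D_G = config$D_G, S_f = config$S_f,
                          kinds = kinds)
  observed <- add_noise(clean, config$noise_cv, config$seed)
  structure(
    list(observed = observed, noise_free = clean, truth_rates = rates,
         config = config),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset (noise_cv =", x$config$noise_cv,
      ", seed =", x$config$seed, ")\n")
  print(x$observed)
  invisible(x)
}

#' Apply multiplicative measurement noise to a time series
#'
#' Each value v becomes `v * (1 + noise_cv * Z)` with standard-normal Z, so
#' the sample coefficient of variation of replicate measurements equals
#' `noise_cv`. Reproducible from `seed`; `noise_cv = 0` returns the input
#' unchanged (bitwise).
#'
#' @param ts a [timeseries_set()]
#' @param noise_cv coefficient of variation, >= 0
#' @param seed integer seed
#' @return a noisy [timeseries_set()]
#' @export
add_noise <- function(ts, noise_cv, seed = 1L) {
  stopifnot(inherits(ts, "timeseries_set"), noise_cv >= 0)
  if (noise_cv == 0) return(ts)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- ts
  for (nm in names(ts$channels)) {
    v <- ts$channels[[nm]]
    noisy <- v * (1 + noise_cv * stats::rnorm(length(v)))
    if (ts$kinds[[nm]] != "direct") noisy <- pmax(noisy, 0)
    out$channels[[nm]] <- noisy
  }
  out
}

#' Post-transient analysis window
#'
#' Recovery statistics exclude the first simulated cycle (the ODE transient
#' is not part of the limit cycle). Returns a copy of the series restricted
#' to `t >= t_start + period_h`.
#'
#' @param ts a [timeseries_set()]
#' @param period_h the configured cycle period, hours
#' @return a trimmed [timeseries_set()]
#' @export
post_transient_window <- function(ts, period_h) {
  stopifnot(inherits(ts, "timeseries_set"))
  keep <- ts$time_h >= ts$time_h[1] + period_h
  if (!any(keep)) stop("no samples after the transient window")
  timeseries_set(ts$time_h[keep], ts$channels[keep, , drop = FALSE],
                 ts$units, D = ts$meta$D, D_G = ts$meta$D_G,
                 S_f = ts$meta$S_f, kinds = ts$kinds)
}
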