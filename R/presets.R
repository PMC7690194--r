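#' Named synthetic-dataset presets
#'
#' The study conditions are version-controlled as YAML preset files under
#' `inst/extdata/presets/`; this loader turns one into a
#' [generator_config()]. Available presets:
#'
#' * `"oscillation"` — sustained 52-h limit cycle at feed 88 g/L and
#'   dilution 0.048 1/h, with the reported stage asymmetry (20 h rising /
#'   32 h falling), the lagged lactate/formate/H2 channels, the leading
#'   CO2/ORP channels and the reported gas and ORP extrema.
#' * `"steady"` — the stable pre-oscillation phase (constant channels,
#'   1,3-PDO 40.66 g/L, butyrate 10.02 g/L).
#' * `"damped"` — reduced feed (44 g/L): oscillation triggers but damps out
#'   (envelope decay 0.012 1/h).
#' * `"no_oscillation"` — doubled dilution rate (0.096 1/h): constant
#'   operation, no oscillation.
#' * `"metabolic_shift"` — the 119-146 h lactate/formate upshift preceding
#'   oscillation onset (lactate 4.26 to 9.07 g/L).
#'
#' @param name preset name (see above)
#' @param t_grid optional replacement sampling grid (hours)
#' @param noise_cv optional replacement measurement-noise CV
#' @param seed optional replacement RNG seed
#' @param damping_rate optional replacement amplitude decay rate (1/h)
#' @return a [generator_config()]
#' @examples
#' cfg <- chemostat_preset("oscillation", noise_cv = 0)
#' sim <- simulate_chemostat(cfg)
#' @export
chemostat_preset <- function(name, t_grid = NULL, noise_cv = NULL,
                             seed = NULL, damping_rate = NULL) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "chemosc")
  if (!nzchar(path)) {
    stop("unknown preset '", name, "'; available: ",
         paste(sub("\\.yaml$", "", list.files(
           system.file("extdata", "presets", package = "chemosc"))),
           collapse = ", "))
  }
  p <- yaml::read_yaml(path)
  if (is.null(t_grid)) {
    t_grid <- seq(p$t_grid$from, p$t_grid$to, by = p$t_grid$by)
  }
  if (is.null(noise_cv)) noise_cv <- p$noise_cv
  if (is.null(seed)) seed <- p$seed
  if (is.null(damping_rate)) damping_rate <- p$damping_rate
  waveforms <- list()
  kinds <- character(0)
  units <- character(0)
  for (nm in names(p$channels)) {
    ch <- p$channels[[nm]]
    rise_h <- if (is.null(ch$rise_h)) p$period_h / 2 else ch$rise_h
    off <- if (is.null(ch$phase_offset_h)) 0 else ch$phase_offset_h
    waveforms[[nm]] <- waveform(p$period_h, rise_h / p$period_h, off,
                                ch$level_min, ch$level_max)
    kinds[nm] <- ch$kind
    units[nm] <- ch$unit
  }
  generator_config(D = p$D, D_G = p$D_G, S_f = p$S_f, t_grid = t_grid,
                   waveforms = waveforms, kinds = kinds, units = units,
                   damping_rate = damping_rate, noise_cv = noise_cv,
                   seed = seed, ref_channel = p$ref_channel)
}
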