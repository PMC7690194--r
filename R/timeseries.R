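#' Aligned multichannel fermentation time series
#'
#' The common currency of the kinetic and oscillation analyses: a strictly
#' increasing time grid (hours) plus named concentration channels with unit
#' tags and the chemostat operating parameters. Typical channels are `X`
#' (biomass, g/L), `glycerol` (residual substrate, g/L), liquid products
#' (`PDO`, `butyrate`, `acetate`, `lactate`, `formate`, g/L), dissolved
#' gases (`H2`, `CO2`, mmol/L) and the online redox probe (`ORP`, mV).
#'
#' @param time_h strictly increasing sampling times, hours
#' @param channels data.frame (or named list) of channel values, one column
#'   per channel, same length as `time_h`
#' @param units named character vector, one unit per channel
#' @param D dilution rate, 1/h
#' @param D_G gas-phase dilution rate, 1/h (`NA` if not applicable)
#' @param S_f substrate feed concentration, g/L
#' @param kinds optional named character vector tagging each channel as one
#'   of `"biomass"`, `"substrate"`, `"product"`, `"gas"`, `"direct"`; used
#'   by the mass-balance machinery. Channels without a tag default to
#'   `"direct"` (no balance).
#' @return object of class `timeseries_set`
#' @export
timeseries_set <- function(time_h, channels, units, D = NA_real_,
                           D_G = NA_real_, S_f = NA_real_, kinds = NULL) {
  time_h <- as.numeric(time_h)
  if (length(time_h) < 1L || anyNA(time_h)) stop("invalid time grid")
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("time grid must be strictly increasing")
  }
  channels <- as.data.frame(channels, optional = TRUE)
  if (nrow(channels) != length(time_h)) {
    stop("channel length does not match the time grid")
  }
  miss <- setdiff(names(channels), names(units))
  if (length(miss)) {
    stop("missing unit tag for channel(s): ", paste(miss, collapse = ", "))
  }
  units <- units[names(channels)]
  if (is.null(kinds)) kinds <- character(0)
  kinds <- vapply(names(channels), function(nm) {
    if (nm %in% names(kinds)) kinds[[nm]] else "direct"
  }, character(1))
  ok <- kinds %in% c("biomass", "substrate", "product", "gas", "direct")
  if (!all(ok)) stop("unknown channel kind: ", paste(kinds[!ok], collapse = ", "))
  neg <- vapply(names(channels), function(nm) {
    kinds[[nm]] != "direct" && any(channels[[nm]] < 0, na.rm = TRUE)
  }, logical(1))
  if (any(neg)) {
    stop("negative concentrations in channel(s): ",
         paste(names(channels)[neg], collapse = ", "))
  }
  structure(
    list(time_h = time_h, channels = channels, units = units, kinds = kinds,
         meta = list(D = D, D_G = D_G, S_f = S_f)),
    class = "timeseries_set"
  )
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat(sprintf("timeseries_set: %d samples, %.1f-%.1f h\n",
              length(x$time_h), min(x$time_h), max(x$time_h)))
  cat("  channels:",
      paste(sprintf("%s [%s]", names(x$channels), x$units), collapse = ", "),
      "\n")
  cat(sprintf("  D = %s 1/h, D_G = %s 1/h, S_f = %s g/L\n",
              format(x$meta$D), format(x$meta$D_G), format(x$meta$S_f)))
  invisible(x)
}

#' Extract one channel as a numeric vector
#' @param ts a [timeseries_set()]
#' @param channel channel name
#' @return numeric vector
#' @export
ts_channel <- function(ts, channel) {
  stopifnot(inherits(ts, "timeseries_set"))
  if (!channel %in% names(ts$channels)) {
    stop("channel not present: ", channel)
  }
  ts$channels[[channel]]
}

#' Write a time series to delimited text
#'
#' One `time_h` column plus one column per channel, header tagged
#' `channel:unit` (e.g. `PDO:g/L`, `H2:mmol/L`, `ORP:mV`). Operating
#' parameters and channel kinds are stored in `#`-prefixed header comments
#' so that [read_timeseries()] round-trips the full object.
#'
#' @param ts a [timeseries_set()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# D=%s D_G=%s S_f=%s",
                     format(ts$meta$D, digits = 15),
                     format(ts$meta$D_G, digits = 15),
                     format(ts$meta$S_f, digits = 15)), con)
  writeLines(paste0("# kinds=", paste(sprintf("%s:%s", names(ts$kinds),
                                              ts$kinds), collapse = ",")),
             con)
  header <- c("time_h", sprintf("%s:%s", names(ts$channels), ts$units))
  writeLines(paste(header, collapse = ","), con)
  mat <- cbind(ts$time_h, as.matrix(ts$channels))
  utils::write.table(format(mat, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a delimited time series written by [write_timeseries()]
#'
#' Validates monotone time, per-channel unit tags and non-negative
#' concentrations; errors carry the offending row or column.
#'
#' @param path input file path
#' @return a [timeseries_set()]
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  meta <- list(D = NA_real_, D_G = NA_real_, S_f = NA_real_)
  kinds <- NULL
  n_hdr <- 0L
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    n_hdr <- n_hdr + 1L
    body <- trimws(sub("^#", "", ln))
    if (startsWith(body, "kinds=")) {
      pairs <- strsplit(strsplit(sub("^kinds=", "", body), ",")[[1]], ":")
      kinds <- vapply(pairs, `[`, character(1), 2)
      names(kinds) <- vapply(pairs, `[`, character(1), 1)
    } else {
      for (kv in strsplit(body, "\\s+")[[1]]) {
        p <- strsplit(kv, "=")[[1]]
        if (p[1] %in% names(meta)) meta[[p[1]]] <- as.numeric(p[2])
      }
    }
  }
  header <- strsplit(lines[n_hdr + 1L], ",")[[1]]
  if (header[1] != "time_h") stop("first column must be 'time_h'")
  specs <- strsplit(header[-1], ":", fixed = TRUE)
  bad <- vapply(specs, length, integer(1)) != 2L
  if (any(bad)) {
    stop("missing unit tag in column header(s): ",
         paste(header[-1][bad], collapse = ", "))
  }
  ch_names <- vapply(specs, `[`, character(1), 1)
  units <- vapply(specs, `[`, character(1), 2)
  names(units) <- ch_names
  dat <- utils::read.csv(textConnection(lines[-seq_len(n_hdr + 1L)]),
                         header = FALSE)
  names(dat) <- c("time_h", ch_names)
  tt <- dat$time_h
  if (is.unsorted(tt, strictly = TRUE)) {
    i <- which(diff(tt) <= 0)[1]
    stop(sprintf("time not strictly increasing at data row %d (t = %g after %g)",
                 i + 1L, tt[i + 1L], tt[i]))
  }
  timeseries_set(tt, dat[ch_names], units,
                 D = meta$D, D_G = meta$D_G, S_f = meta$S_f, kinds = kinds)
}
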