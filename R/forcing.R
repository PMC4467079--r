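#' Synthesize a growing-season PPFD forcing series
#'
#' Builds a regular time series of photosynthetic photon flux density as
#' a stand-in for subarctic June-July meteorology: each day is a
#' truncated half-sine of the stated daylight length centered at solar
#' noon with amplitude `peak`, plus optional Gaussian noise clipped at
#' zero.  Defaults (61 days at 1800 s, peak 800 umol m-2 s-1, 20 h
#' daylight) sketch a high-latitude growing season; this generator is a
#' synthetic stand-in, not observed station data, so absolute seasonal
#' GPP totals driven by it are not comparable to totals from real
#' forcing.
#'
#' @param n_days Number of days (>= 1).
#' @param timestep_s Timestep in seconds (must divide the day evenly).
#' @param peak Solar-noon PPFD, umol photons m-2 s-1 (> 0).
#' @param daylight_hours Daylight duration, in (0, 24].
#' @param noise_sd Standard deviation of additive Gaussian noise; the
#'   series is clipped at zero afterwards.  Default 0 (deterministic).
#' @param seed Optional integer seed for the noise.
#' @param start First timestamp (midnight of day one), POSIXct.
#'
#' @return A `ppfd_series`: data frame with columns `timestamp`
#'   (POSIXct, UTC) and `ppfd`, with a `timestep` attribute in seconds.
#' @examples
#' f <- synthesize_ppfd(n_days = 2)
#' max(f$ppfd)    # = peak, at solar noon
#' @export
synthesize_ppfd <- function(n_days = 61L, timestep_s = 1800L, peak = 800,
                            daylight_hours = 20, noise_sd = 0, seed = NULL,
                            start = as.POSIXct("2007-06-01 00:00:00",
                                               tz = "UTC")) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("`n_days` must be >= 1")
  if (!is.finite(timestep_s) || timestep_s <= 0 ||
      86400 %% timestep_s != 0) {
    stop("`timestep_s` must be positive and divide 86400 evenly")
  }
  if (!is.finite(peak) || peak <= 0) stop("`peak` must be > 0")
  if (!is.finite(daylight_hours) || daylight_hours <= 0 ||
      daylight_hours > 24) {
    stop("`daylight_hours` must be in (0, 24]")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")

  steps_per_day <- as.integer(86400 / timestep_s)
  n <- n_days * steps_per_day
  t_sec <- (seq_len(n) - 1L) * as.numeric(timestep_s)
  tod_h <- (t_sec %% 86400) / 3600                  # hours since midnight
  phase <- (tod_h - 12) / daylight_hours            # 0 at solar noon
  ppfd <- ifelse(abs(phase) <= 0.5, peak * cos(pi * phase), 0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ppfd <- pmax(ppfd + stats::rnorm(n, sd = noise_sd), 0)
  }
  out <- data.frame(timestamp = start + t_sec, ppfd = ppfd)
  structure(out, timestep = as.numeric(timestep_s),
            class = c("ppfd_series", "data.frame"))
}

#' @export
print.ppfd_series <- function(x, ...) {
  cat(sprintf(paste0("<ppfd_series> %d steps of %.6g s (%.3g days), ",
                     "peak %.4g umol m-2 s-1\n"),
              nrow(x), attr(x, "timestep"),
              nrow(x) * attr(x, "timestep") / 86400, max(x$ppfd)))
  invisible(x)
}

#' @export
plot.ppfd_series <- function(x, ...) {
  graphics::plot(x$timestamp, x$ppfd, type = "l", xlab = "time",
                 ylab = "PPFD (umol m-2 s-1)", ...)
  invisible(x)
}

## check the ppfd_series contract; infers the timestep when absent
validate_ppfd <- function(forcing) {
  if (!is.data.frame(forcing) || !all(c("timestamp", "ppfd") %in%
                                        names(forcing))) {
    stop("forcing must be a data frame with columns `timestamp` and `ppfd`")
  }
  if (nrow(forcing) == 0L) stop("forcing series is empty")
  if (any(!is.finite(forcing$ppfd))) stop("forcing contains non-finite PPFD")
  neg <- which(forcing$ppfd < 0)
  if (length(neg)) {
    stop(sprintf("negative PPFD at row %d (%s)", neg[1],
                 format(forcing$timestamp[neg[1]])))
  }
  dt <- attr(forcing, "timestep")
  if (nrow(forcing) > 1L) {
    steps <- as.numeric(diff(as.numeric(forcing$timestamp)))
    if (max(steps) - min(steps) > 1e-6 * max(steps) || any(steps <= 0)) {
      stop("forcing timestamps are not regularly spaced and increasing")
    }
    if (is.null(dt)) dt <- steps[1]
  } else if (is.null(dt)) {
    stop("single-row forcing needs an explicit `timestep` attribute")
  }
  attr(forcing, "timestep") <- dt
  if (!inherits(forcing, "ppfd_series")) {
    class(forcing) <- c("ppfd_series", class(forcing))
  }
  forcing
}

#' Read / write a PPFD forcing series as CSV
#'
#' The file has two columns, `timestamp` (ISO-8601, assumed UTC) and
#' `ppfd`, at a constant timestep.  Reading validates regular spacing
#' and non-negative values; writing uses full float precision.
#'
#' @param path File path.
#' @return `read_ppfd_csv` returns a validated `ppfd_series`.
#' @export
read_ppfd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("forcing file is empty: ", path)
  if (!all(c("timestamp", "ppfd") %in% names(df))) {
    stop("forcing CSV must have columns `timestamp` and `ppfd`")
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(ts))) {
    stop(sprintf("unparseable timestamp at row %d", which(is.na(ts))[1]))
  }
  validate_ppfd(data.frame(timestamp = ts, ppfd = as.numeric(df$ppfd)))
}

#' @rdname read_ppfd_csv
#' @param forcing A `ppfd_series`.
#' @export
write_ppfd_csv <- function(forcing, path) {
  forcing <- validate_ppfd(forcing)
  df <- data.frame(
    timestamp = format(forcing$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    ppfd = formatC(forcing$ppfd, format = "g", digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
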