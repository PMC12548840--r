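#' Butterworth filter specification
#'
#' @param order filter order per pass; must be even and at least 2
#'   (default 4).
#' @param cutoff_hz low-pass cutoff frequency; the conventional choices are
#'   10 Hz for kinematics and 100 Hz for force-plate data.
#' @param sampling_hz sampling rate of the series to be filtered.
#' @export
filter_spec <- function(order = 4, cutoff_hz, sampling_hz) {
  if (order < 2 || order %% 2 != 0) {
    stop("filter order must be even and >= 2", call. = FALSE)
  }
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_hz / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         sampling_hz / 2, " Hz)", call. = FALSE)
  }
  structure(list(order = order, cutoff_hz = cutoff_hz,
                 sampling_hz = sampling_hz), class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an `order`-th order Butterworth low-pass filter forward and
#' backward (zero phase lag, magnitude response squared). Before filtering,
#' the series is extended at both ends by odd reflection to suppress
#' start-up transients; the padding is removed afterwards, so the output has
#' the same length as the input.
#'
#' @param x a uniformly sampled numeric series.
#' @param spec a [filter_spec()].
#' @return the filtered series.
#' @export
butterworth_lowpass <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n < 3 * spec$order) {
    stop("series too short: need at least ", 3 * spec$order,
         " samples for an order-", spec$order, " zero-phase filter",
         call. = FALSE)
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$sampling_hz / 2),
                       type = "low")
  pad <- min(n - 1L, max(3L * (spec$order + 1L), 24L))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(front, x, back)
  ## steady-state initial conditions at the first padded sample (DC gain 1)
  pass <- function(v) {
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], length(bf$b) - 1L),
                              init.y = rep(v[1], length(bf$a) - 1L)))
  }
  y <- rev(pass(rev(pass(xe))))
  y[(pad + 1):(pad + n)]
}

## Filter every coordinate column of a wide marker table (columns
## <LABEL>_X/_Y/_Z) at the kinematic cutoff.
filter_marker_table <- function(markers, spec) {
  out <- markers
  for (cc in setdiff(names(markers), c("frame", "time_s"))) {
    out[[cc]] <- butterworth_lowpass(markers[[cc]], spec)
  }
  out
}
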