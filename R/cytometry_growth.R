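#' Construct a flow-cytometry sample
#'
#' Per-event fluorescence and side scatter for one sample. Side scatter
#' tracks cell size/granularity and collapses for dead or lysed cells, so
#' it is used both as a normalizer and an implicit viability filter.
#'
#' @param fluor Per-event fluorescence (a.u.).
#' @param ssc Per-event side scatter (a.u.), same length.
#' @param label Sample label.
#' @return An object of class `flow_sample`.
#' @export
flow_sample <- function(fluor, ssc, label = "sample") {
  if (length(fluor) != length(ssc)) stop("channel lengths differ")
  structure(list(fluor = as.numeric(fluor), ssc = as.numeric(ssc),
                 label = label, n_events = length(fluor)),
            class = "flow_sample")
}

#' Median side-scatter-normalized fluorescence
#'
#' Each event's fluorescence is divided by its side scatter before taking
#' the median across events; events with non-positive side scatter are
#' dropped first. Dividing by side scatter suppresses the contribution of
#' dead cells (low scatter, low signal) to the sample summary, and the
#' median resists whatever subpopulation remains.
#'
#' @param sample A [flow_sample()]; at least 100 retained events.
#' @return Scalar median normalized fluorescence.
#' @export
normalized_median <- function(sample) {
  stopifnot(inherits(sample, "flow_sample"))
  keep <- sample$ssc > 0
  if (sum(keep) < 100) stop("fewer than 100 events after filtering")
  stats::median(sample$fluor[keep] / sample$ssc[keep])
}

#' Reporter fold-change series from flow samples
#'
#' Summarizes each time point's sample by its side-scatter-normalized
#' median and divides by the value at the reference time.
#'
#' @param samples Named or unnamed list of [flow_sample()] objects, one
#'   per time point, in time order.
#' @param times Times (min) matching `samples`.
#' @param reference_time Time of the pre-stress reference (default 0);
#'   must be present in `times`.
#' @return Data frame with columns `time_min`, `median_norm`,
#'   `fold_change`.
#' @export
fold_change_series <- function(samples, times, reference_time = 0) {
  if (length(samples) != length(times)) stop("samples and times differ")
  i_ref <- match(reference_time, times)
  if (is.na(i_ref)) stop("reference time not present")
  med <- vapply(samples, normalized_median, numeric(1))
  if (med[i_ref] <= 0) stop("reference median must be > 0")
  data.frame(time_min = times, median_norm = med,
             fold_change = med / med[i_ref])
}

#' Construct an OD600 growth series
#'
#' @param times Times (min); typically 20-minute spacing over 24 hours.
#' @param od OD600 values (> 0), same length; at least 20 points.
#' @param replicate Replicate identifier.
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(times, od, replicate = 1L) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (length(times) < 20) stop("need at least 20 points")
  if (any(od <= 0)) stop("OD600 must be > 0")
  structure(list(times = times, od = od, replicate = replicate),
            class = "growth_series")
}

#' Maximal growth rate after the temperature shift
#'
#' Smooths the OD series with a 3-point moving average, estimates the
#' derivative by central finite differences, and returns the maximum
#' derivative over the window starting at the temperature-shift time --
#' the log-phase growth rate at the elevated temperature.
#'
#' @param series A [growth_series()].
#' @param shift_time Time of the temperature shift (min; default 240, a
#'   4-hour pre-growth phase).
#' @return A list with `rate` (OD/min) and `time` (min, where the maximum
#'   derivative occurs).
#' @export
max_growth_rate <- function(series, shift_time = 240) {
  stopifnot(inherits(series, "growth_series"))
  t <- series$times
  od <- series$od
  n <- length(od)
  smooth <- od
  smooth[2:(n - 1)] <- (od[1:(n - 2)] + od[2:(n - 1)] + od[3:n]) / 3
  deriv <- rep(NA_real_, n)
  deriv[2:(n - 1)] <- (smooth[3:n] - smooth[1:(n - 2)]) /
    (t[3:n] - t[1:(n - 2)])
  deriv[1] <- (smooth[2] - smooth[1]) / (t[2] - t[1])
  deriv[n] <- (smooth[n] - smooth[n - 1]) / (t[n] - t[n - 1])
  window <- which(t >= shift_time)
  if (length(window) < 3) stop("too few points after the shift time")
  i_max <- window[which.max(deriv[window])]
  list(rate = deriv[i_max], time = t[i_max])
}
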