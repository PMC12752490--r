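#' Respiratory flow trace
#'
#' A uniformly sampled respiratory flow signal. The sign convention throughout
#' the package is expiration-positive: positive flow is gas leaving the
#' blowhole, negative flow is inspiration.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing
#'   on a uniform grid.
#' @param flow numeric vector of flow in l s^-1 (expiration positive), same
#'   length as `time`.
#' @param sample_rate sampling rate in Hz. The grid spacing must equal
#'   `1/sample_rate` to within 1e-9 s.
#' @param calibration optional [calibration_result()] attached after flow
#'   calibration; `NULL` for raw traces.
#'
#' @return An object of class `flow_trace`: a list with elements `time`,
#'   `flow`, `sample_rate`, `calibration`.
#' @seealso [gas_trace()], [calibrate_flow()], [detect_breaths()]
#' @export
flow_trace <- function(time, flow, sample_rate, calibration = NULL) {
  stopifnot(is.numeric(time), is.numeric(flow), length(time) == length(flow))
  if (length(time) < 2L) stop("a flow trace needs at least two samples")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (any(abs(dt - 1 / sample_rate) > 1e-9))
    stop("time grid is not uniform at 1/sample_rate spacing")
  structure(
    list(time = as.numeric(time), flow = as.numeric(flow),
         sample_rate = sample_rate, calibration = calibration),
    class = "flow_trace"
  )
}

#' Expired gas-fraction trace
#'
#' Dry O2 and CO2 fractions sub-sampled at the blowhole, with the analyzer
#' response-time and transport-delay metadata needed for phase alignment and
#' deconvolution.
#'
#' @param time numeric sample times in seconds (uniform grid).
#' @param fo2,fco2 dry gas fractions in \[0, 1\]; `fo2 + fco2` must not
#'   exceed 1.
#' @param sample_rate sampling rate in Hz.
#' @param t90_o2,t90_co2 analyzer response times (s) for a 90% change to
#'   equilibrium, per channel.
#' @param transport_delay gas transport delay through the sampling line (s).
#'
#' @return An object of class `gas_trace`.
#' @export
gas_trace <- function(time, fo2, fco2, sample_rate,
                      t90_o2 = 0.067, t90_co2 = 0.094,
                      transport_delay = 0) {
  stopifnot(length(time) == length(fo2), length(time) == length(fco2))
  if (any(fo2 < 0 | fo2 > 1) || any(fco2 < 0 | fco2 > 1))
    stop("gas fractions must lie in [0, 1]")
  if (any(fo2 + fco2 > 1 + 1e-12)) stop("fo2 + fco2 must not exceed 1")
  if (t90_o2 <= 0 || t90_co2 <= 0) stop("t90 values must be > 0")
  if (transport_delay < 0) stop("transport_delay must be >= 0")
  dt <- diff(time)
  if (any(dt <= 0) || any(abs(dt - 1 / sample_rate) > 1e-9))
    stop("time grid is not uniform at 1/sample_rate spacing")
  structure(
    list(time = as.numeric(time), fo2 = as.numeric(fo2),
         fco2 = as.numeric(fco2), sample_rate = sample_rate,
         t90_o2 = t90_o2, t90_co2 = t90_co2,
         transport_delay = transport_delay),
    class = "gas_trace"
  )
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %d samples at %g Hz (%.1f s), flow %g..%g l/s%s\n",
              length(x$time), x$sample_rate, diff(range(x$time)),
              round(min(x$flow), 3), round(max(x$flow), 3),
              if (is.null(x$calibration)) ", uncalibrated" else ", calibrated"))
  invisible(x)
}

#' @export
print.gas_trace <- function(x, ...) {
  cat(sprintf(
    "<gas_trace> %d samples at %g Hz; t90 O2 %g s, CO2 %g s; delay %g s\n",
    length(x$time), x$sample_rate, x$t90_o2, x$t90_co2, x$transport_delay))
  invisible(x)
}

# shared time-base check used by operations taking both traces
check_shared_grid <- function(flow, gas) {
  if (length(flow$time) != length(gas$time) ||
      max(abs(flow$time - gas$time)) > 1e-9 ||
      abs(flow$sample_rate - gas$sample_rate) > 1e-9)
    stop("flow and gas traces do not share a time base")
  invisible(TRUE)
}
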