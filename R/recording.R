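#' Two-channel LFP recording
#'
#' Container for a pair of synchronized voltage traces (left and right
#' cortex) sampled at a fixed interval, with the sample index of the event
#' (e.g. CSD induction) marking time zero.
#'
#' @param left,right Numeric voltage series (volts), equal length.
#' @param dt Sampling interval in seconds (default 0.001, i.e. 1 kHz).
#' @param t0_index 1-based sample index corresponding to event time t = 0.
#' @param labels Character vector of two channel names.
#' @return An object of class `raw_recording`: a list with elements `left`,
#'   `right`, `dt`, `t0_index`, `labels`.
#' @examples
#' rec <- raw_recording(rnorm(2000), rnorm(2000), dt = 0.001, t0_index = 1000)
#' rec
#' @export
raw_recording <- function(left, right, dt = 0.001, t0_index = 1L,
                          labels = c("left", "right")) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right))
    stop("channels must have equal length")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar")
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > length(left))
    stop("t0_index out of range")
  if (anyNA(left) || anyNA(right))
    stop("channels must be finite")
  structure(
    list(left = left, right = right, dt = dt, t0_index = t0_index,
         labels = as.character(labels)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- length(x$left)
  cat(sprintf(
    "<raw_recording> %d samples x 2 channels (%s, %s), dt = %g s (%.4g s total)\n",
    n, x$labels[1], x$labels[2], x$dt, n * x$dt))
  cat(sprintf("  t = 0 at sample %d (%.4g s before end)\n",
              x$t0_index, (n - x$t0_index) * x$dt))
  invisible(x)
}

#' @export
length.raw_recording <- function(x) length(x$left)

#' Time axis of a recording
#'
#' @param rec A `raw_recording` or `detrended_recording`.
#' @return Numeric vector of times in seconds, zero at the event marker.
#' @export
recording_time <- function(rec) {
  (seq_along(rec$left) - rec$t0_index) * rec$dt
}

new_detrended_recording <- function(residual_left, residual_right,
                                    trend_left, trend_right, dt, t0_index,
                                    labels) {
  structure(
    list(left = residual_left, right = residual_right,
         trend_left = trend_left, trend_right = trend_right,
         dt = dt, t0_index = t0_index, labels = labels),
    class = c("detrended_recording")
  )
}

#' @export
print.detrended_recording <- function(x, ...) {
  cat(sprintf(
    "<detrended_recording> %d samples x 2 channels, dt = %g s\n",
    length(x$left), x$dt))
  cat("  components: residual (AC, f >~ 0.5 Hz) + trend (DC moving average)\n")
  invisible(x)
}
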