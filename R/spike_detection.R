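# Spike detection from raw extracellular traces: zero-phase Butterworth
# high-pass, robust noise-floor estimate, then +/- k SD threshold crossings
# timestamped at the local extremum.

#' Spike detection parameters
#'
#' @param highpass_cutoff High-pass cutoff frequency in Hz (default 100).
#' @param threshold_k Detection threshold in multiples of the noise SD
#'   (default 4.5, applied as +/- `threshold_k` SD).
#' @param dead_time Refractory window in seconds during which subsequent
#'   threshold crossings are suppressed (default 1.5 ms).
#' @param polarity Which crossings count: `"both"` (default), `"negative"`
#'   or `"positive"`.
#' @param noise_method `"mad"` (default): scaled median absolute deviation,
#'   robust to the spikes themselves; `"sd"`: plain standard deviation.
#' @param order Butterworth filter order (default 2, applied forward and
#'   backward for zero phase).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(highpass_cutoff = 100, threshold_k = 4.5,
                             dead_time = 0.0015,
                             polarity = c("both", "negative", "positive"),
                             noise_method = c("mad", "sd"), order = 2L) {
  polarity <- match.arg(polarity)
  noise_method <- match.arg(noise_method)
  if (highpass_cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (threshold_k <= 0) stop("threshold_k must be positive", call. = FALSE)
  if (dead_time < 0) stop("dead_time must be non-negative", call. = FALSE)
  structure(
    list(highpass_cutoff = highpass_cutoff, threshold_k = threshold_k,
         dead_time = dead_time, polarity = polarity,
         noise_method = noise_method, order = as.integer(order)),
    class = "detection_params"
  )
}

#' Zero-phase Butterworth high-pass filter
#'
#' Filters the trace forward and backward (via [signal::filtfilt()]) so spike
#' timing is preserved; length and sampling rate are unchanged.
#'
#' @param trace A [raw_trace()].
#' @param params A [detection_params()].
#' @return The filtered [raw_trace()].
#' @export
highpass_filter <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "raw_trace"))
  nyq <- trace$sampling_rate / 2
  if (params$highpass_cutoff >= nyq) {
    stop("high-pass cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(params$order, params$highpass_cutoff / nyq,
                       type = "high")
  # remove the mean first: the DC component is rejected exactly and the
  # forward-backward pass sees no step at the trace edges
  trace$samples <- signal::filtfilt(bf, trace$samples - mean(trace$samples))
  trace
}

#' Robust noise SD of a filtered trace
#'
#' Scaled median absolute deviation (MAD / 0.6745), which tracks the Gaussian
#' noise floor even when a small fraction of samples belongs to spikes; set
#' `method = "sd"` for the plain standard deviation.
#'
#' @param trace A [raw_trace()] (after high-pass filtering).
#' @param method `"mad"` (default) or `"sd"`.
#' @return Estimated noise SD in microvolts; 0 (with a warning) for an
#'   all-zero trace.
#' @export
estimate_noise_sd <- function(trace, method = c("mad", "sd")) {
  stopifnot(inherits(trace, "raw_trace"))
  method <- match.arg(method)
  x <- trace$samples
  if (all(x == 0)) {
    warning("all-zero trace: noise SD is 0")
    return(0)
  }
  if (method == "mad") stats::mad(x, constant = 1.4826) else stats::sd(x)
}

#' Detect spikes by noise-scaled threshold crossing
#'
#' A spike is registered when the absolute (or one-signed, per `polarity`)
#' sample exceeds `threshold_k` times the estimated noise SD.  The spike is
#' timestamped at the extremum within 1 ms after the crossing, and subsequent
#' crossings within `dead_time` of an accepted spike are suppressed.
#'
#' @param trace A [raw_trace()], already high-pass filtered.
#' @param params A [detection_params()].
#' @param noise_sd Optional precomputed noise SD; estimated from the trace by
#'   [estimate_noise_sd()] when missing.
#' @return A [spike_train()] (possibly empty) spanning the trace duration.
#' @export
detect_spikes <- function(trace, params = detection_params(),
                          noise_sd = NULL) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$samples
  fs <- trace$sampling_rate
  duration <- length(x) / fs
  if (is.null(noise_sd)) {
    noise_sd <- suppressWarnings(estimate_noise_sd(trace, params$noise_method))
  }
  if (noise_sd <= 0) {
    return(spike_train(numeric(0), duration, trace$electrode_id))
  }
  thr <- params$threshold_k * noise_sd
  over <- switch(params$polarity,
                 both = abs(x) > thr,
                 negative = x < -thr,
                 positive = x > thr)
  crossings <- which(over & !c(FALSE, over[-length(over)]))
  if (length(crossings) == 0L) {
    return(spike_train(numeric(0), duration, trace$electrode_id))
  }
  win <- max(1L, round(0.001 * fs))
  dead <- params$dead_time
  times <- numeric(0)
  last <- -Inf
  for (i in crossings) {
    t_cross <- (i - 1) / fs
    if (t_cross - last < dead) next
    idx <- i:min(i + win, length(x))
    peak <- idx[which.max(abs(x[idx]))]
    t_peak <- (peak - 1) / fs
    if (length(times) && t_peak <= times[length(times)]) next
    times <- c(times, t_peak)
    last <- t_cross
  }
  spike_train(times, duration, trace$electrode_id)
}
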