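# Single-channel burst detection with the logISI method: the logarithmic
# inter-spike-interval histogram separates intra-burst from inter-burst
# intervals; an adaptive threshold is placed in the valley between the
# intra-burst peak and the first later peak sufficiently "void" of counts,
# and bursts are maximal runs of spikes whose ISIs stay below the threshold.

#' Burst detection parameters
#'
#' @param min_spikes Minimum spikes per burst (default 5).
#' @param max_isi_cap Upper cap on the intra-burst ISI threshold in seconds
#'   (default 0.100 s); the adaptive threshold never exceeds it and it is the
#'   fallback when no valley qualifies.
#' @param bursting_channel_rate Burst rate (bursts/s) at or above which a
#'   channel counts as a bursting channel (default 0.4; inclusive boundary).
#' @param void_threshold Minimum void parameter for a valley to separate the
#'   intra-burst peak from a later peak (default 0.7).
#' @param bins_per_decade Histogram resolution of the log10-ISI axis
#'   (default 10).
#' @param smooth_window Centered moving-average window, in bins, applied to
#'   the histogram before peak finding (default 3).
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(min_spikes = 5L, max_isi_cap = 0.100,
                         bursting_channel_rate = 0.4, void_threshold = 0.7,
                         bins_per_decade = 10L, smooth_window = 3L) {
  if (min_spikes < 2) stop("min_spikes must be >= 2", call. = FALSE)
  if (max_isi_cap <= 0) stop("max_isi_cap must be positive", call. = FALSE)
  if (bursting_channel_rate <= 0) {
    stop("bursting_channel_rate must be positive", call. = FALSE)
  }
  if (void_threshold <= 0 || void_threshold > 1) {
    stop("void_threshold must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(min_spikes = as.integer(min_spikes), max_isi_cap = max_isi_cap,
         bursting_channel_rate = bursting_channel_rate,
         void_threshold = void_threshold,
         bins_per_decade = as.integer(bins_per_decade),
         smooth_window = as.integer(smooth_window)),
    class = "burst_params"
  )
}

#' Logarithmic inter-spike-interval histogram
#'
#' Histogram of log10(ISI) over uniform log bins spanning the observed ISI
#' range, smoothed by a centered moving average (partial windows at the
#' edges).  Counts always sum to the number of ISIs (`n_spikes - 1`).
#'
#' @param train A [spike_train()] with at least 2 spikes; with fewer, an
#'   empty-histogram sentinel is returned.
#' @param bins_per_decade Bins per decade of the log10 axis.
#' @param smooth_window Moving-average window in bins.
#' @return An object of class `isi_histogram`: list with `bin_edges` (log10
#'   seconds), `counts`, `smoothed`, `n_isi` and logical `empty`.
#' @export
log_isi_histogram <- function(train, bins_per_decade = 10L,
                              smooth_window = 3L) {
  stopifnot(inherits(train, "spike_train"))
  isi <- diff(train$spike_times)
  if (length(isi) < 1L) {
    return(structure(list(bin_edges = numeric(0), counts = integer(0),
                          smoothed = numeric(0), n_isi = 0L, empty = TRUE),
                     class = "isi_histogram"))
  }
  lo <- log10(min(isi))
  hi <- log10(max(isi))
  step <- 1 / bins_per_decade
  edges <- seq(floor(lo / step) * step, ceiling(hi / step) * step + step / 2,
               by = step)
  if (length(edges) < 2L) edges <- c(edges, edges + step)
  bins <- findInterval(log10(isi), edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  counts <- tabulate(bins, nbins = length(edges) - 1L)
  smoothed <- moving_average(counts, smooth_window)
  structure(list(bin_edges = edges, counts = counts, smoothed = smoothed,
                 n_isi = length(isi), empty = FALSE),
            class = "isi_histogram")
}

# centered moving average with shrunken windows at the edges
moving_average <- function(x, window = 3L) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, 0)
}

# strict-ish local maxima of a smoothed histogram (plateaus collapse to the
# first bin)
local_maxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  which(vapply(seq_len(n), function(i) {
    if (s[i] <= 0) return(FALSE)
    left <- if (i == 1L) -Inf else s[i - 1L]
    right <- if (i == n) -Inf else s[i + 1L]
    s[i] > left && s[i] >= right
  }, TRUE))
}

#' Adaptive intra-burst ISI threshold from a logISI histogram
#'
#' The dominant smoothed peak (the histogram's global maximum) is taken as
#' the intra-burst peak, provided it lies below `max_isi_cap` — a channel
#' whose dominant ISI mode is slower than the cap has no intra-burst regime
#' and uses the fallback.  Moving rightwards, the first later peak whose valley has a void
#' parameter `1 - h_min / sqrt(h_peak1 * h_peak2)` at or above
#' `void_threshold` qualifies; the threshold is the ISI at the deepest
#' minimum between the two peaks, capped at `max_isi_cap`.  If there is no
#' intra-burst peak or no qualifying valley, `max_isi_cap` is returned with
#' attribute `fallback = TRUE`.
#'
#' @param hist An [log_isi_histogram()] result.
#' @param params A [burst_params()].
#' @return Threshold in seconds (never above `max_isi_cap`), with a logical
#'   `fallback` attribute.
#' @export
find_isi_threshold <- function(hist, params = burst_params()) {
  stopifnot(inherits(hist, "isi_histogram"))
  cap <- params$max_isi_cap
  fallback <- structure(cap, fallback = TRUE)
  if (hist$empty) return(fallback)
  s <- hist$smoothed
  centers <- (hist$bin_edges[-1L] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  peaks <- local_maxima(s)
  if (length(peaks) == 0L) return(fallback)
  # the intra-burst peak must be the dominant ISI mode: a channel whose
  # largest smoothed peak sits at or above the cap (e.g. a stationary Poisson
  # train, mode at its mean) has no intra-burst regime and falls back, and
  # chance clusters of a few short ISIs cannot masquerade as one
  p1 <- peaks[which.max(s[peaks])]
  if (centers[p1] >= log10(cap)) return(fallback)
  later <- peaks[peaks > p1]
  for (p2 in later) {
    between <- (p1 + 1L):(p2 - 1L)
    if (length(between) == 0L || p2 - p1 < 2L) next
    h_min <- min(s[between])
    void <- 1 - h_min / sqrt(s[p1] * s[p2])
    if (void >= params$void_threshold) {
      i_min <- between[which.min(s[between])]
      thr <- 10^centers[i_min]
      return(structure(min(thr, cap), fallback = FALSE))
    }
  }
  fallback
}

#' Detect bursts as runs of closely spaced spikes
#'
#' Maximal runs of consecutive spikes whose inter-spike intervals are all at
#' or below `isi_threshold`, kept when the run holds at least
#' `params$min_spikes` spikes.  Burst start/end are the first/last spike
#' times of the run.
#'
#' @param train A [spike_train()].
#' @param isi_threshold Intra-burst ISI threshold in seconds, e.g. from
#'   [find_isi_threshold()].
#' @param params A [burst_params()].
#' @return A data frame with columns `electrode_id`, `start`, `end`,
#'   `n_spikes`, one row per burst, ordered by start time.
#' @export
detect_bursts <- function(train, isi_threshold, params = burst_params()) {
  stopifnot(inherits(train, "spike_train"), isi_threshold > 0)
  t <- train$spike_times
  empty <- data.frame(electrode_id = character(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0))
  if (length(t) < params$min_spikes) return(empty)
  ok <- diff(t) <= isi_threshold
  r <- rle(ok)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= params$min_spikes)
  if (!any(keep)) return(empty)
  first_spike <- starts_idx[keep]          # run of ISIs i..j spans spikes i..j+1
  last_spike <- ends_idx[keep] + 1L
  data.frame(
    electrode_id = train$electrode_id,
    start = t[first_spike],
    end = t[last_spike],
    n_spikes = last_spike - first_spike + 1L
  )
}

#' Full logISI burst detection for one train
#'
#' Convenience wrapper: histogram, adaptive threshold, then run scan.
#'
#' @inheritParams detect_bursts
#' @return As [detect_bursts()], with the threshold used attached as
#'   attribute `isi_threshold`.
#' @export
train_bursts <- function(train, params = burst_params()) {
  h <- log_isi_histogram(train, params$bins_per_decade, params$smooth_window)
  thr <- find_isi_threshold(h, params)
  b <- detect_bursts(train, as.numeric(thr), params)
  attr(b, "isi_threshold") <- as.numeric(thr)
  b
}

#' Burst rate and bursting-channel classification
#'
#' @param bursts Burst data frame from [detect_bursts()].
#' @param duration Recording duration in seconds.
#' @param params A [burst_params()]; a channel is bursting when its rate is
#'   at or above `bursting_channel_rate` (inclusive).
#' @return List with `rate` (bursts/s) and logical `is_bursting`.
#' @export
channel_burst_stats <- function(bursts, duration, params = burst_params()) {
  stopifnot(duration > 0)
  rate <- nrow(bursts) / duration
  list(rate = rate, is_bursting = rate >= params$bursting_channel_rate)
}
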