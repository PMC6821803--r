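#' Spike train for a single electrode
#'
#' Bundles the sorted spike times recorded on one extracellular electrode
#' together with the recording duration.  All times are in seconds, 0-based
#' from the start of the recording.
#'
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`.  May be empty: an electrode with
#'   zero spikes is an explicit empty train, not a missing one.
#' @param duration Recording duration in seconds (> 0).
#' @param electrode_id,well_id Character identifiers.
#'
#' @return An object of class `spike_train`: a list with elements
#'   `electrode_id`, `well_id`, `spike_times` and `duration`.
#' @export
#' @examples
#' st <- spike_train(c(0.1, 0.2, 0.35), duration = 10)
#' n_spikes(st)
spike_train <- function(spike_times, duration, electrode_id = "E01",
                        well_id = "W01") {
  spike_times <- as.numeric(spike_times)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  if (anyNA(spike_times) || any(!is.finite(spike_times))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(spike_times) > 0L &&
      (spike_times[1L] < 0 || spike_times[length(spike_times)] > duration)) {
    stop("spike times must lie within [0, duration]", call. = FALSE)
  }
  structure(
    list(
      electrode_id = as.character(electrode_id),
      well_id = as.character(well_id),
      spike_times = spike_times,
      duration = duration
    ),
    class = "spike_train"
  )
}

#' Number of spikes in a spike train
#' @param train A [spike_train()].
#' @return Integer spike count.
#' @export
n_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$spike_times)
}

#' Firing rate of a spike train
#' @param train A [spike_train()].
#' @return Spikes per second (Hz).
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$spike_times) / train$duration
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s/%s: %d spikes in %.1f s (%.3f Hz)\n",
              x$well_id, x$electrode_id, length(x$spike_times), x$duration,
              length(x$spike_times) / x$duration))
  invisible(x)
}

#' Recording of one MEA well
#'
#' Collects the spike trains of all electrodes of one well (12 electrodes per
#' well in the default 24-well layout).  All trains must share one duration;
#' missing electrodes are represented by absence, not by empty trains.
#'
#' @param trains List of [spike_train()] objects with unique electrode ids and
#'   a common duration.
#' @param well_id Character well identifier.
#' @param group_label Optional group/condition label (e.g. `"control"`).
#' @param div Optional age of the culture in days in vitro.
#' @param n_electrodes Number of electrodes physically present in the well
#'   (default 12); `length(trains)` may not exceed it.
#'
#' @return An object of class `well_recording`.
#' @export
well_recording <- function(trains, well_id = "W01", group_label = NA_character_,
                           div = NA_integer_, n_electrodes = 12L) {
  if (!is.list(trains) || !all(vapply(trains, inherits, TRUE, "spike_train"))) {
    stop("`trains` must be a list of spike_train objects", call. = FALSE)
  }
  if (length(trains) > n_electrodes) {
    stop("more trains than electrodes in the well", call. = FALSE)
  }
  ids <- vapply(trains, function(t) t$electrode_id, "")
  if (anyDuplicated(ids)) {
    stop("electrode ids must be unique within a well", call. = FALSE)
  }
  durs <- vapply(trains, function(t) t$duration, 0)
  if (length(durs) > 0L && diff(range(durs)) > 0) {
    stop("all trains in a well must share one duration", call. = FALSE)
  }
  names(trains) <- ids
  structure(
    list(
      well_id = as.character(well_id),
      group_label = as.character(group_label),
      div = as.integer(div),
      trains = trains,
      duration = if (length(durs)) durs[1L] else NA_real_,
      n_electrodes = as.integer(n_electrodes)
    ),
    class = "well_recording"
  )
}

#' @export
print.well_recording <- function(x, ...) {
  cat(sprintf("<well_recording> %s [%s]: %d/%d electrodes, %.0f s\n",
              x$well_id, x$group_label, length(x$trains), x$n_electrodes,
              x$duration))
  invisible(x)
}

#' Recording of a full multi-well MEA plate
#'
#' @param wells List of [well_recording()] objects with unique well ids.
#' @param plate_id Character plate identifier.
#'
#' @return An object of class `plate_recording`.
#' @export
plate_recording <- function(wells, plate_id = "P01") {
  if (!is.list(wells) || !all(vapply(wells, inherits, TRUE, "well_recording"))) {
    stop("`wells` must be a list of well_recording objects", call. = FALSE)
  }
  ids <- vapply(wells, function(w) w$well_id, "")
  if (anyDuplicated(ids)) stop("well ids must be unique", call. = FALSE)
  names(wells) <- ids
  structure(
    list(plate_id = as.character(plate_id), wells = wells),
    class = "plate_recording"
  )
}

#' @export
print.plate_recording <- function(x, ...) {
  cat(sprintf("<plate_recording> %s: %d wells\n", x$plate_id, length(x$wells)))
  invisible(x)
}

#' Raw extracellular voltage trace
#'
#' @param samples Numeric vector of voltages in microvolts.
#' @param sampling_rate Sampling rate in Hz (10 kHz in the reference
#'   acquisition setup).
#' @param electrode_id Character electrode identifier.
#'
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, sampling_rate, electrode_id = "E01") {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      electrode_id = as.character(electrode_id),
      samples = samples,
      sampling_rate = sampling_rate
    ),
    class = "raw_trace"
  )
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %s: %d samples at %g Hz (%.2f s)\n",
              x$electrode_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Patch-clamp sweep
#'
#' A single current (pA) or voltage (mV) sweep with an attached stimulus time
#' and holding potential, as recorded in whole-cell experiments.
#'
#' @param samples Numeric vector (picoamperes for voltage-clamp current
#'   sweeps, millivolts for current-clamp voltage sweeps).
#' @param sampling_rate Sampling rate in Hz.
#' @param stim_time Stimulus (or current-step) onset in seconds from sweep
#'   start; must fall inside the sweep.
#' @param holding_potential Holding potential in mV (`NA` for current clamp).
#'
#' @return An object of class `sweep`.
#' @export
ephys_sweep <- function(samples, sampling_rate, stim_time,
                  holding_potential = NA_real_) {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  len_s <- length(samples) / sampling_rate
  if (stim_time < 0 || stim_time > len_s) {
    stop("`stim_time` must lie within the sweep", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sampling_rate = sampling_rate,
      stim_time = stim_time,
      holding_potential = as.numeric(holding_potential)
    ),
    class = "sweep"
  )
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %d samples at %g Hz, stim at %.3f s, Vh = %s mV\n",
              length(x$samples), x$sampling_rate, x$stim_time,
              format(x$holding_potential)))
  invisible(x)
}

# time axis of a sweep or raw trace, seconds from sweep start
sweep_times <- function(x) (seq_along(x$samples) - 1) / x$sampling_rate
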