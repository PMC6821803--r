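# Network-burst detection and well-level metrics.  A network burst is a
# synchronous event built from closely spaced single-channel bursts that
# recruits strictly more than 80% of the well's active channels.

#' Active electrodes of a well
#'
#' An electrode is active when its overall firing rate is at or above
#' `min_rate` (inclusive boundary).
#'
#' @param well A [well_recording()].
#' @param min_rate Minimum firing rate in Hz (default 0.1).
#' @return Character vector of active electrode ids.
#' @export
active_electrodes <- function(well, min_rate = 0.1) {
  stopifnot(inherits(well, "well_recording"), min_rate >= 0)
  rates <- vapply(well$trains, firing_rate, 0)
  names(rates)[rates >= min_rate]
}

#' Mean firing rate over active electrodes
#'
#' Arithmetic mean of the per-channel firing rate across the active
#' electrodes; `NA` (not zero) when no electrode is active.
#'
#' @param well A [well_recording()].
#' @param active Character vector of active electrode ids, from
#'   [active_electrodes()].
#' @return Mean firing rate in Hz, or `NA_real_` if `active` is empty.
#' @export
mean_firing_rate <- function(well, active = active_electrodes(well)) {
  stopifnot(inherits(well, "well_recording"))
  if (length(active) == 0L) {
    warning("no active electrodes: mean firing rate undefined")
    return(NA_real_)
  }
  mean(vapply(well$trains[active], firing_rate, 0))
}

#' Detect network bursts from single-channel bursts
#'
#' Bursts on active channels are pooled and merged transitively whenever
#' their intervals overlap or the gap between them is at most `merge_gap`.
#' A merged candidate becomes a network burst iff its distinct participating
#' channels exceed `participation` times the number of active channels
#' (strict inequality: with 10 active channels, 9 participating channels
#' qualify, 8 do not at the default 0.8).
#'
#' @param channel_bursts Data frame of single-channel bursts (columns
#'   `electrode_id`, `start`, `end`, `n_spikes`), e.g. rows bound from
#'   [train_bursts()] over the well's electrodes.
#' @param active Character vector of active electrode ids; bursts on other
#'   channels are ignored.  Fewer than 2 active channels yields an empty
#'   result with a warning.
#' @param participation Required fraction of active channels (default 0.8,
#'   strict).
#' @param merge_gap Maximum gap in seconds between consecutive channel bursts
#'   of one event (default 0.1).
#' @return Data frame with columns `start`, `end`, `n_channels`, `n_spikes`,
#'   one row per network burst, ordered by start.
#' @export
detect_network_bursts <- function(channel_bursts, active,
                                  participation = 0.8, merge_gap = 0.1) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_channels = integer(0), n_spikes = integer(0))
  if (length(active) < 2L) {
    warning("fewer than 2 active channels: no network bursts defined")
    return(empty)
  }
  cb <- channel_bursts[channel_bursts$electrode_id %in% active, , drop = FALSE]
  if (nrow(cb) == 0L) return(empty)
  cb <- cb[order(cb$start), , drop = FALSE]
  # transitive merge of overlapping / closely spaced intervals
  grp <- integer(nrow(cb))
  grp[1L] <- 1L
  cur_end <- cb$end[1L]
  for (i in seq_len(nrow(cb))[-1L]) {
    if (cb$start[i] <= cur_end + merge_gap) {
      grp[i] <- grp[i - 1L]
      cur_end <- max(cur_end, cb$end[i])
    } else {
      grp[i] <- grp[i - 1L] + 1L
      cur_end <- cb$end[i]
    }
  }
  need <- participation * length(active)
  events <- lapply(split(seq_len(nrow(cb)), grp), function(idx) {
    chans <- unique(cb$electrode_id[idx])
    if (length(chans) > need) {
      data.frame(start = min(cb$start[idx]), end = max(cb$end[idx]),
                 n_channels = length(chans),
                 n_spikes = sum(cb$n_spikes[idx]))
    }
  })
  events <- events[!vapply(events, is.null, TRUE)]
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Network-burst rate, duration and interval statistics
#'
#' Network burst durations (NBD) are `end - start`; network inter-burst
#' intervals (NIBI) run from the end of one network burst to the start of the
#' next.  Histograms use 100 ms (NBD) and 1 s (NIBI) bins by default.
#'
#' @param nbs Network bursts from [detect_network_bursts()].
#' @param duration Recording duration in seconds.
#' @param nbd_bin,nibi_bin Histogram bin widths in seconds.
#' @return List with `nb_rate` (bursts/min), `nbd` and `nibi` vectors,
#'   `mean_nbd`, `sd_nbd`, `mean_nibi`, `sd_nibi`, and histograms
#'   `nbd_hist` / `nibi_hist` (as from [hist()], not plotted).  With fewer
#'   than 2 network bursts the NIBI fields are empty/`NA`.
#' @export
network_burst_stats <- function(nbs, duration, nbd_bin = 0.1, nibi_bin = 1) {
  stopifnot(duration > 0)
  n <- nrow(nbs)
  nbd <- nbs$end - nbs$start
  nibi <- if (n >= 2L) nbs$start[-1L] - nbs$end[-n] else numeric(0)
  hist_of <- function(x, bin) {
    if (length(x) == 0L) return(NULL)
    breaks <- seq(0, max(x) + bin, by = bin)
    graphics::hist(x, breaks = breaks, plot = FALSE)
  }
  list(
    nb_rate = n * 60 / duration,
    nbd = nbd,
    nibi = nibi,
    mean_nbd = if (n) mean(nbd) else NA_real_,
    sd_nbd = if (n > 1L) stats::sd(nbd) else NA_real_,
    mean_nibi = if (length(nibi)) mean(nibi) else NA_real_,
    sd_nibi = if (length(nibi) > 1L) stats::sd(nibi) else NA_real_,
    nbd_hist = hist_of(nbd, nbd_bin),
    nibi_hist = hist_of(nibi, nibi_bin)
  )
}

#' Coefficient of variation of network inter-burst intervals
#'
#' Population standard deviation divided by the mean: the irregularity
#' measure of the network-burst rhythm.
#'
#' @param nibis Numeric vector of inter-burst intervals in seconds.
#' @return Dimensionless CV, or `NA_real_` with fewer than 2 intervals or a
#'   non-positive mean.
#' @export
cv_nibi <- function(nibis) {
  if (length(nibis) < 2L) return(NA_real_)
  m <- mean(nibis)
  if (m <= 0) return(NA_real_)
  sqrt(mean((nibis - m)^2)) / m
}

# counts of active-electrode spikes inside/outside network-burst windows;
# inside + outside == total holds by construction
count_spikes_in_nbs <- function(well, active, nbs) {
  t_all <- sort(unlist(lapply(well$trains[active],
                              function(tr) tr$spike_times), use.names = FALSE))
  total <- length(t_all)
  if (total == 0L || nrow(nbs) == 0L) {
    return(list(inside = 0L, outside = total, total = total))
  }
  idx <- findInterval(t_all, nbs$start)
  inside <- sum(idx >= 1L & t_all <= nbs$end[pmax(idx, 1L)])
  list(inside = inside, outside = total - inside, total = total)
}

#' Percentage of spikes outside network bursts
#'
#' Fraction (as a percent) of all spikes on active electrodes that fall
#' outside every network-burst window.
#'
#' @param well A [well_recording()].
#' @param active Active electrode ids.
#' @param nbs Network bursts from [detect_network_bursts()].
#' @return Percent in `[0, 100]`; `NA_real_` when there are no spikes on
#'   active electrodes.
#' @export
pct_spikes_outside <- function(well, active, nbs) {
  cnt <- count_spikes_in_nbs(well, active, nbs)
  if (cnt$total == 0L) {
    warning("no spikes on active electrodes")
    return(NA_real_)
  }
  100 * cnt$outside / cnt$total
}

#' Well-level network metric vector
#'
#' Runs the full pipeline on one well: active-electrode selection, logISI
#' burst detection per channel, network-burst detection, then the metric
#' vector used for phenotype characterization.
#'
#' @param well A [well_recording()] of spike trains.
#' @param burst_par A [burst_params()].
#' @param min_rate Active-electrode rate threshold in Hz.
#' @param participation,merge_gap Network-burst parameters, see
#'   [detect_network_bursts()].
#' @return A one-row data frame with columns `well_id`, `group_label`,
#'   `n_active`, `mfr` (Hz), `nb_rate` (bursts/min), `mean_nbd` (s),
#'   `mean_nibi` (s), `cv_nibi`, `pct_outside` (percent).  Undefined
#'   quantities propagate as `NA`.
#' @export
summarize_well <- function(well, burst_par = burst_params(), min_rate = 0.1,
                           participation = 0.8, merge_gap = 0.1) {
  stopifnot(inherits(well, "well_recording"))
  active <- active_electrodes(well, min_rate)
  mfr <- suppressWarnings(mean_firing_rate(well, active))
  cb <- do.call(rbind, lapply(well$trains[active], train_bursts,
                              params = burst_par))
  if (is.null(cb)) {
    cb <- data.frame(electrode_id = character(0), start = numeric(0),
                     end = numeric(0), n_spikes = integer(0))
  }
  nbs <- suppressWarnings(
    detect_network_bursts(cb, active, participation, merge_gap)
  )
  st <- network_burst_stats(nbs, well$duration)
  data.frame(
    well_id = well$well_id,
    group_label = well$group_label,
    n_active = length(active),
    mfr = mfr,
    nb_rate = st$nb_rate,
    mean_nbd = st$mean_nbd,
    mean_nibi = st$mean_nibi,
    cv_nibi = cv_nibi(st$nibi),
    pct_outside = suppressWarnings(pct_spikes_outside(well, active, nbs)),
    stringsAsFactors = FALSE
  )
}

#' Metric table for a whole plate
#'
#' @param plate A [plate_recording()].
#' @param ... Passed to [summarize_well()].
#' @return Data frame with one row per well.
#' @export
summarize_plate <- function(plate, ...) {
  stopifnot(inherits(plate, "plate_recording"))
  out <- do.call(rbind, lapply(plate$wells, summarize_well, ...))
  rownames(out) <- NULL
  out
}
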