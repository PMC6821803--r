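# Synthetic MEA and patch-clamp data with known ground truth.
#
# The well generator produces rhythmic network bursts: burst onsets follow a
# gamma renewal process (independently tunable mean and CV), burst durations
# are gamma, each active channel participates in each burst with a fixed
# probability and fires a homogeneous Poisson train inside the burst window,
# and background spikes are homogeneous Poisson on active channels.

#' Configuration of a synthetic MEA well
#'
#' @param duration Recording duration in seconds (default 1200 s = 20 min).
#' @param n_electrodes Electrodes per well (default 12).
#' @param active_fraction Fraction of electrodes carrying activity, in (0, 1].
#' @param mean_nibi Mean network inter-burst interval (end of one network
#'   burst to start of the next), seconds.
#' @param cv_nibi Coefficient of variation of the inter-burst gap
#'   (dimensionless, > 0): the irregularity axis of the bursting rhythm.
#' @param mean_nbd Mean network burst duration, seconds; must be below
#'   `mean_nibi`.
#' @param nbd_cv Coefficient of variation of the burst duration (0 gives
#'   constant durations).
#' @param participation_p Probability that an active channel joins a given
#'   burst, in (0, 1].
#' @param intra_burst_rate Per-channel Poisson firing rate inside a burst, Hz.
#' @param background_rate Per-channel Poisson background rate outside bursts,
#'   Hz (background spikes are laid over the whole recording).
#' @param seed Integer seed used by [simulate_well()] unless overridden.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(duration = 1200, n_electrodes = 12L,
                              active_fraction = 1, mean_nibi = 15,
                              cv_nibi = 0.3, mean_nbd = 1, nbd_cv = 0.2,
                              participation_p = 0.95, intra_burst_rate = 60,
                              background_rate = 1, seed = 1L) {
  cfg <- list(
    duration = duration, n_electrodes = as.integer(n_electrodes),
    active_fraction = active_fraction, mean_nibi = mean_nibi,
    cv_nibi = cv_nibi, mean_nbd = mean_nbd, nbd_cv = nbd_cv,
    participation_p = participation_p, intra_burst_rate = intra_burst_rate,
    background_rate = background_rate, seed = as.integer(seed)
  )
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("active_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!(mean_nibi > mean_nbd) || mean_nbd < 0) {
    stop("need mean_nibi > mean_nbd >= 0", call. = FALSE)
  }
  if (cv_nibi <= 0 || nbd_cv < 0) {
    stop("cv_nibi must be > 0 and nbd_cv >= 0", call. = FALSE)
  }
  if (participation_p <= 0 || participation_p > 1) {
    stop("participation_p must be in (0, 1]", call. = FALSE)
  }
  if (intra_burst_rate < 0 || background_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_config> %.0f s, %d electrodes (%.0f%% active)\n",
           "  NIBI %.1f s (CV %.2f), NBD %.2f s (CV %.2f)\n",
           "  participation %.2f, intra-burst %.0f Hz, background %.2f Hz\n"),
    x$duration, x$n_electrodes, 100 * x$active_fraction, x$mean_nibi,
    x$cv_nibi, x$mean_nbd, x$nbd_cv, x$participation_p, x$intra_burst_rate,
    x$background_rate))
  invisible(x)
}

# gamma draws parameterized by mean and CV; cv = 0 degenerates to the mean
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean * cv^2)
}

#' Control-like preset configuration
#'
#' Emulates a mature, regularly network-bursting culture: frequent short
#' network bursts, a regular rhythm, and a sizeable fraction of spikes
#' falling outside network bursts.
#'
#' @return A [simulation_config()].
#' @seealso [ks_preset()]
#' @export
control_preset <- function() {
  simulation_config(mean_nibi = 15, cv_nibi = 0.3, mean_nbd = 1,
                    background_rate = 1)
}

#' KS-like preset configuration
#'
#' Differs from [control_preset()] only in the phenotype axes: longer and
#' more irregular inter-burst intervals (lower network-burst rate, higher CV),
#' longer burst durations, and less background spiking (a smaller percentage
#' of spikes outside network bursts).
#'
#' @return A [simulation_config()].
#' @export
ks_preset <- function() {
  simulation_config(mean_nibi = 40, cv_nibi = 0.7, mean_nbd = 3,
                    background_rate = 0.3)
}

#' Simulate one MEA well with ground truth
#'
#' The network-burst skeleton alternates gamma-distributed inter-burst gaps
#' (mean `mean_nibi`, CV `cv_nibi`; gamma shape `1/cv^2`, scale
#' `mean * cv^2`) with gamma-distributed burst durations (mean `mean_nbd`,
#' CV `nbd_cv`), so consecutive bursts never overlap and the end-to-start
#' inter-burst interval of the generated recording has exactly the
#' configured mean and CV in expectation.  Active channels participate in each burst with probability
#' `participation_p`, firing homogeneous Poisson spikes at `intra_burst_rate`
#' inside the window; background spikes are Poisson at `background_rate` over
#' the whole recording.  Inactive channels get explicit empty trains.  Output
#' is fully reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @param well_id,group_label Identifiers attached to the returned well.
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A list with elements `well` (a [well_recording()]) and `truth`, a
#'   list with `nb_onsets`, `nb_offsets` (seconds) and `spikes`, a data frame
#'   of every generated spike with columns `electrode_id`, `time`, `label`
#'   (`"in_burst"` or `"background"`).
#' @export
simulate_well <- function(config, well_id = "W01", group_label = NA_character_,
                          seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  dur <- config$duration

  # burst skeleton: alternate gamma inter-burst gaps and gamma durations, so
  # the end-to-start NIBI of the generated train is exactly the parameterized
  # quantity (sample mean/CV converge to mean_nibi/cv_nibi)
  cycle_mean <- config$mean_nibi + config$mean_nbd
  n_draw <- ceiling(dur / cycle_mean * 3) + 20L
  gaps <- rgamma_mean_cv(n_draw, config$mean_nibi, config$cv_nibi)
  nb_dur <- rgamma_mean_cv(n_draw, config$mean_nbd, config$nbd_cv)
  onsets <- numeric(0)
  offsets <- numeric(0)
  t0 <- gaps[1L] # initial delay drawn from the gap distribution
  for (i in seq_len(n_draw - 1L)) {
    if (t0 >= dur) break
    onsets <- c(onsets, t0)
    offsets <- c(offsets, min(t0 + nb_dur[i], dur))
    t0 <- offsets[length(offsets)] + gaps[i + 1L]
  }
  keep <- offsets > onsets
  onsets <- onsets[keep]
  offsets <- offsets[keep]
  n_nb <- length(onsets)

  n_active <- max(1L, round(config$active_fraction * config$n_electrodes))
  eids <- sprintf("E%02d", seq_len(config$n_electrodes))

  spike_rows <- vector("list", config$n_electrodes)
  trains <- vector("list", config$n_electrodes)
  for (e in seq_len(config$n_electrodes)) {
    if (e <= n_active) {
      times <- numeric(0)
      labels <- character(0)
      if (n_nb > 0L && config$intra_burst_rate > 0) {
        joins <- stats::runif(n_nb) <= config$participation_p
        for (b in which(joins)) {
          nk <- stats::rpois(1L, config$intra_burst_rate *
                               (offsets[b] - onsets[b]))
          if (nk > 0L) {
            times <- c(times, stats::runif(nk, onsets[b], offsets[b]))
            labels <- c(labels, rep("in_burst", nk))
          }
        }
      }
      if (config$background_rate > 0) {
        nbg <- stats::rpois(1L, config$background_rate * dur)
        if (nbg > 0L) {
          times <- c(times, stats::runif(nbg, 0, dur))
          labels <- c(labels, rep("background", nbg))
        }
      }
      ord <- order(times)
      times <- times[ord]
      labels <- labels[ord]
      dup <- duplicated(times)
      if (any(dup)) {
        times <- times[!dup]
        labels <- labels[!dup]
      }
      trains[[e]] <- spike_train(times, duration = dur, electrode_id = eids[e],
                                 well_id = well_id)
      spike_rows[[e]] <- if (length(times)) {
        data.frame(electrode_id = eids[e], time = times, label = labels,
                   stringsAsFactors = FALSE)
      }
    } else {
      trains[[e]] <- spike_train(numeric(0), duration = dur,
                                 electrode_id = eids[e], well_id = well_id)
    }
  }

  well <- well_recording(trains, well_id = well_id, group_label = group_label,
                         n_electrodes = config$n_electrodes)
  truth <- list(
    nb_onsets = onsets,
    nb_offsets = offsets,
    spikes = do.call(rbind, spike_rows[!vapply(spike_rows, is.null, TRUE)])
  )
  list(well = well, truth = truth)
}

#' Simulate a plate of wells from one configuration
#'
#' Convenience wrapper around [simulate_well()]: well `i` is generated with
#' seed `seed + i - 1`, so a plate is reproducible from a single seed.
#'
#' @param config A [simulation_config()].
#' @param n_wells Number of wells.
#' @param group_label Label attached to every well.
#' @param seed Base seed.
#' @param plate_id Plate identifier.
#' @return A list with `plate` (a [plate_recording()]) and `truths` (a list of
#'   per-well ground-truth lists, named by well).
#' @export
simulate_plate <- function(config, n_wells = 10L, group_label = NA_character_,
                           seed = config$seed, plate_id = "P01") {
  wells <- vector("list", n_wells)
  truths <- vector("list", n_wells)
  for (i in seq_len(n_wells)) {
    wid <- sprintf("%s_W%02d", if (is.na(group_label)) "sim" else group_label, i)
    sim <- simulate_well(config, well_id = wid, group_label = group_label,
                         seed = seed + i - 1L)
    wells[[i]] <- sim$well
    truths[[i]] <- sim$truth
    names(truths)[i] <- wid
  }
  list(plate = plate_recording(wells, plate_id = plate_id), truths = truths)
}

#' Default biphasic extracellular spike template
#'
#' A short negative-leading biphasic waveform whose largest deflection is
#' `amplitude` microvolts, placed at the third sample so that detected
#' extremum times track the nominal spike time closely.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param amplitude Peak (most negative) amplitude in microvolts.
#' @param width Total template width in seconds (default 1.2 ms).
#' @return Numeric vector of microvolts.
#' @export
spike_waveform <- function(sampling_rate = 10000, amplitude = -60,
                           width = 0.0012) {
  n <- max(6L, round(width * sampling_rate))
  t <- seq(0, 1, length.out = n)
  # negative lobe peaking early, smaller positive rebound; scaled so the
  # extreme sample equals `amplitude`
  w <- -exp(-((t - 0.2) / 0.12)^2) + 0.35 * exp(-((t - 0.55) / 0.18)^2)
  w * (amplitude / w[which.max(abs(w))])
}

#' Simulate a raw extracellular trace from a spike train
#'
#' Additive Gaussian noise plus a waveform template inserted at each spike
#' time; overlapping templates are summed (with a warning).
#'
#' @param train A [spike_train()].
#' @param waveform Template in microvolts, e.g. [spike_waveform()]; must be
#'   shorter than the smallest inter-spike interval for non-overlapping
#'   insertion.
#' @param noise_sd Gaussian noise SD in microvolts.
#' @param sampling_rate Sampling rate in Hz (>= 10 kHz).
#' @param seed Optional integer seed for the noise.
#' @return A [raw_trace()] covering `train$duration`.
#' @export
simulate_raw_trace <- function(train, waveform = spike_waveform(sampling_rate),
                               noise_sd = 5, sampling_rate = 10000,
                               seed = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(train$duration * sampling_rate)
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  wl <- length(waveform)
  if (length(train$spike_times) > 1L &&
      min(diff(train$spike_times)) < wl / sampling_rate) {
    warning("overlapping spike waveforms; amplitudes are summed")
  }
  for (t in train$spike_times) {
    i0 <- floor(t * sampling_rate) + 1L
    idx <- i0:min(i0 + wl - 1L, n)
    x[idx] <- x[idx] + waveform[seq_along(idx)]
  }
  raw_trace(x, sampling_rate, electrode_id = train$electrode_id)
}

# sample indices of a window [from, to) in seconds relative to the stimulus;
# shared by the evoked simulator and the ratio quantifier so that a noiseless
# constructed pair recovers its amplitudes exactly
window_index <- function(sweep, from, to) {
  tt <- sweep_times(sweep) - sweep$stim_time
  which(tt >= from - 1e-12 & tt < to - 1e-12)
}

#' Simulate a baseline-aligned evoked AMPA/NMDA sweep pair
#'
#' The -70 mV sweep holds a fast inward difference-of-exponentials synaptic
#' current whose sampled peak equals `ampa_amp`; the +40 mV sweep holds a slow
#' outward current scaled so that its mean over the 65-70 ms post-stimulus
#' window equals `nmda_amp` before noise.  Baseline is zero.
#'
#' @param ampa_amp Peak AMPA amplitude in pA, negative (inward at -70 mV).
#' @param nmda_amp NMDA window amplitude in pA, non-negative (outward at
#'   +40 mV).
#' @param tau_decay NMDA decay time constant in seconds.
#' @param noise_sd Gaussian noise SD in pA added to both sweeps.
#' @param sampling_rate Sampling rate in Hz.
#' @param sweep_duration Sweep length in seconds.
#' @param stim_time Stimulus time in seconds from sweep start.
#' @param seed Optional integer seed for the noise.
#' @return An object of class `evoked_pair`: a list with [ephys_sweep()] elements
#'   `sweep_minus70`, `sweep_plus40` and the `baseline_window` (seconds of
#'   pre-stimulus baseline used downstream).
#' @export
simulate_evoked_pair <- function(ampa_amp, nmda_amp, tau_decay = 0.08,
                                 noise_sd = 0, sampling_rate = 10000,
                                 sweep_duration = 0.5, stim_time = 0.1,
                                 seed = NULL) {
  if (ampa_amp >= 0) stop("`ampa_amp` must be negative (inward current)",
                          call. = FALSE)
  if (nmda_amp < 0) stop("`nmda_amp` must be non-negative", call. = FALSE)
  if (tau_decay <= 0) stop("`tau_decay` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- round(sweep_duration * sampling_rate)
  tt <- (seq_len(n) - 1) / sampling_rate - stim_time
  post <- pmax(tt, 0)

  # fast AMPA: rise 2 ms, decay 10 ms -> peak ~5 ms post-stimulus
  ampa <- (exp(-post / 0.010) - exp(-post / 0.002)) * (tt >= 0)
  m70 <- ephys_sweep(numeric(n), sampling_rate, stim_time, holding_potential = -70)
  ampa <- ampa / max(ampa) # unit positive peak on the sampled grid
  m70$samples <- ampa * ampa_amp

  # slow NMDA: rise 5 ms, decay tau_decay
  nmda <- (exp(-post / tau_decay) - exp(-post / 0.005)) * (tt >= 0)
  p40 <- ephys_sweep(numeric(n), sampling_rate, stim_time, holding_potential = 40)
  widx <- window_index(p40, 0.065, 0.070)
  wmean <- mean(nmda[widx])
  p40$samples <- if (wmean > 0) nmda * (nmda_amp / wmean) else nmda * 0

  if (noise_sd > 0) {
    m70$samples <- m70$samples + stats::rnorm(n, 0, noise_sd)
    p40$samples <- p40$samples + stats::rnorm(n, 0, noise_sd)
  }
  structure(
    list(sweep_minus70 = m70, sweep_plus40 = p40, baseline_window = 0.05),
    class = "evoked_pair"
  )
}
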