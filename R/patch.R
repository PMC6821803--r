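# Single-cell electrophysiology quantification: sEPSC event-burst
# statistics, evoked NMDA/AMPA ratio, NMDA decay constant, passive membrane
# properties from a hyperpolarizing step, and action-potential features.

#' Detect bursts of synaptic events
#'
#' Fixed-threshold run scan over event times: a burst is a run of at least
#' `min_events` events whose inter-event intervals are all at or below
#' `iei_threshold` (100 ms by default), the same scan semantics as
#' [detect_bursts()] without the adaptive logISI step.
#'
#' @param event_times Increasing event times in seconds.
#' @param duration Recording duration in seconds.
#' @param min_events Minimum events per burst (default 5).
#' @param iei_threshold Maximum within-burst inter-event interval in seconds
#'   (default 0.100).
#' @return List with `bursts` (data frame `start`, `end`, `n_events`),
#'   `burst_rate` (bursts/s) and `mean_duration` (s, `NA` with no bursts).
#' @export
detect_event_bursts <- function(event_times, duration, min_events = 5L,
                                iei_threshold = 0.100) {
  train <- spike_train(event_times, duration, electrode_id = "cell")
  b <- detect_bursts(train, iei_threshold,
                     burst_params(min_spikes = min_events))
  bursts <- data.frame(start = b$start, end = b$end, n_events = b$n_spikes)
  list(
    bursts = bursts,
    burst_rate = nrow(bursts) / duration,
    mean_duration = if (nrow(bursts)) mean(bursts$end - bursts$start)
                    else NA_real_
  )
}

#' Pointwise average of sweeps
#'
#' @param sweeps List of [ephys_sweep()] objects sharing length, sampling rate and
#'   stimulus time.
#' @param n Number of leading sweeps to average (default: all).
#' @return A [ephys_sweep()] holding the pointwise mean.
#' @export
average_sweeps <- function(sweeps, n = length(sweeps)) {
  stopifnot(all(vapply(sweeps, inherits, TRUE, "sweep")))
  if (length(sweeps) < n) {
    stop(sprintf("need %d sweeps, got %d", n, length(sweeps)), call. = FALSE)
  }
  sweeps <- sweeps[seq_len(n)]
  lens <- vapply(sweeps, function(s) length(s$samples), 0L)
  rates <- vapply(sweeps, function(s) s$sampling_rate, 0)
  stims <- vapply(sweeps, function(s) s$stim_time, 0)
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L ||
      length(unique(stims)) != 1L) {
    stop("sweeps must share length, sampling rate and stimulus time",
         call. = FALSE)
  }
  out <- sweeps[[1L]]
  out$samples <- rowMeans(vapply(sweeps, function(s) s$samples,
                                 numeric(lens[1L])))
  out
}

# mean of the pre-stimulus baseline window
baseline_mean <- function(sw, baseline_window) {
  idx <- window_index(sw, -baseline_window, 0)
  if (length(idx) == 0L) stop("no baseline samples before the stimulus",
                              call. = FALSE)
  mean(sw$samples[idx])
}

#' NMDA/AMPA ratio from an evoked sweep pair
#'
#' Both sweeps are baseline-subtracted (mean of the pre-stimulus baseline
#' window).  The AMPA amplitude is the most negative value of the -70 mV
#' sweep in the post-stimulus peak-search window (2-50 ms by default, the
#' first 2 ms blanked against the stimulus artifact); the NMDA amplitude is
#' the mean of the +40 mV sweep over 65-70 ms after the stimulus, a window
#' late enough to avoid contamination by the fast AMPA component.  The ratio
#' is `|nmda| / |ampa|`.
#'
#' @param pair An `evoked_pair` (e.g. [simulate_evoked_pair()]), or any list
#'   with [ephys_sweep()] elements `sweep_minus70`, `sweep_plus40` and a
#'   `baseline_window` in seconds.
#' @param ampa_window Post-stimulus search window for the AMPA peak, seconds.
#' @param nmda_window Post-stimulus averaging window for NMDA, seconds.
#' @param qc_floor Minimum acceptable `|ampa|` in pA (default 25); smaller
#'   amplitudes set the `qc_pass` flag to `FALSE`.
#' @return List with `ampa_amp` (pA, signed), `nmda_amp` (pA, signed),
#'   `ratio` (`NA` when the AMPA amplitude is zero) and logical `qc_pass`.
#' @export
nmda_ampa_ratio <- function(pair, ampa_window = c(0.002, 0.050),
                            nmda_window = c(0.065, 0.070), qc_floor = 25) {
  m70 <- pair$sweep_minus70
  p40 <- pair$sweep_plus40
  bw <- pair$baseline_window
  y70 <- m70$samples - baseline_mean(m70, bw)
  y40 <- p40$samples - baseline_mean(p40, bw)
  a_idx <- window_index(m70, ampa_window[1L], ampa_window[2L])
  n_idx <- window_index(p40, nmda_window[1L], nmda_window[2L])
  ampa <- min(y70[a_idx])
  nmda <- mean(y40[n_idx])
  ratio <- if (abs(ampa) == 0) NA_real_ else abs(nmda) / abs(ampa)
  list(ampa_amp = ampa, nmda_amp = nmda, ratio = ratio,
       qc_pass = abs(ampa) >= qc_floor)
}

#' Decay time constant of an evoked current
#'
#' Locates the post-stimulus extremum of the baseline-subtracted sweep and
#' fits a single exponential `A * exp(-(t - t0)/tau)` by nonlinear least
#' squares from the point where the current has fallen to `from_fraction`
#' of the peak down to baseline.
#'
#' @param sw A [ephys_sweep()].
#' @param from_fraction Fraction of the peak at which the fit starts
#'   (default 0.9).
#' @param baseline_window Pre-stimulus baseline window in seconds.
#' @return Decay constant tau in seconds.
#' @export
fit_decay_tau <- function(sw, from_fraction = 0.9, baseline_window = 0.05) {
  stopifnot(inherits(sw, "sweep"))
  y <- sw$samples - baseline_mean(sw, baseline_window)
  tt <- sweep_times(sw)
  post <- which(tt >= sw$stim_time)
  yp <- y[post]
  tp <- tt[post]
  i_peak <- which.max(abs(yp))
  s <- sign(yp[i_peak])
  yp <- yp * s # positive-going from here on
  peak <- yp[i_peak]
  if (peak <= 0) stop("no identifiable peak after the stimulus", call. = FALSE)
  after <- seq(i_peak, length(yp))
  i_start <- after[which(yp[after] <= from_fraction * peak)[1L]]
  if (is.na(i_start)) stop("trace does not decay after the peak", call. = FALSE)
  # fit down to where the current reaches 2% of the peak (or sweep end)
  below <- after[after >= i_start & yp[after] <= 0.02 * peak]
  i_end <- if (length(below)) below[1L] else length(yp)
  if (i_end - i_start < 5L) stop("decay segment too short to fit",
                                 call. = FALSE)
  seg_t <- tp[i_start:i_end] - tp[i_start]
  seg_y <- yp[i_start:i_end]
  tau0 <- max(seg_t[which(seg_y <= seg_y[1L] / exp(1))[1L]], 0.005,
              na.rm = TRUE)
  fit <- try(minpack.lm::nlsLM(
    seg_y ~ A * exp(-seg_t / tau),
    start = list(A = seg_y[1L], tau = tau0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) stop("exponential decay fit failed",
                                       call. = FALSE)
  tau <- stats::coef(fit)[["tau"]]
  if (tau <= 0) stop("exponential decay fit failed", call. = FALSE)
  tau
}

#' Passive membrane properties from a hyperpolarizing current step
#'
#' Input resistance is the steady-state voltage deflection divided by the
#' injected current (Ohm's law); the membrane time constant comes from a
#' single-exponential fit of the charging transient after step onset.
#'
#' @param step_sweep A voltage [ephys_sweep()] in mV whose `stim_time` marks the
#'   step onset.
#' @param injected_current Step current in pA (default -25, hyperpolarizing;
#'   must be non-zero).
#' @param step_duration Step length in seconds (default 0.5).
#' @param baseline_window Pre-step baseline window in seconds.
#' @return List with `rin_mohm` (input resistance, megaohms), `tau_s`
#'   (membrane time constant, seconds) and logical `steady` (`FALSE`, with a
#'   warning, when the late plateau still drifts).
#' @export
passive_properties <- function(step_sweep, injected_current = -25,
                               step_duration = 0.5, baseline_window = 0.05) {
  stopifnot(inherits(step_sweep, "sweep"))
  if (injected_current == 0) stop("injected current must be non-zero",
                                  call. = FALSE)
  v0 <- baseline_mean(step_sweep, baseline_window)
  y <- step_sweep$samples - v0
  tt <- sweep_times(step_sweep) - step_sweep$stim_time
  in_step <- which(tt >= 0 & tt < step_duration)
  if (length(in_step) < 20L) stop("step window not inside the sweep",
                                  call. = FALSE)
  # steady state: last 20% of the step
  late <- in_step[tt[in_step] >= 0.8 * step_duration]
  dv <- mean(y[late])
  # drift check: first vs second half of the plateau
  half <- length(late) %/% 2L
  drift <- abs(mean(y[late[seq_len(half)]]) -
                 mean(y[late[(half + 1L):length(late)]]))
  steady <- drift <= max(0.05 * abs(dv), 1e-9)
  if (!steady) warning("no steady state reached during the step")
  rin_mohm <- dv / injected_current * 1000 # mV/pA = GOhm

  seg <- in_step[tt[in_step] <= min(0.4 * step_duration, 0.2)]
  seg_t <- tt[seg]
  seg_y <- y[seg]
  fit <- try(minpack.lm::nlsLM(
    seg_y ~ Vinf * (1 - exp(-seg_t / tau)),
    start = list(Vinf = dv, tau = 0.02),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  tau <- if (inherits(fit, "try-error")) NA_real_
         else stats::coef(fit)[["tau"]]
  list(rin_mohm = rin_mohm, tau_s = tau, steady = steady)
}

#' Action-potential features from a rheobase sweep
#'
#' Threshold is the membrane potential at the first crossing of the dV/dt
#' criterion (20 V/s by default); amplitude is peak minus threshold;
#' half-width is the width at half amplitude; decay time runs from the peak
#' down to the half-amplitude level on the falling phase.
#'
#' @param sw A voltage [ephys_sweep()] in mV containing at least one action
#'   potential after `stim_time`.
#' @param threshold_dvdt dV/dt criterion in V/s (default 20).
#' @return List with `threshold_mv`, `amplitude_mv`, `half_width_s`,
#'   `decay_time_s`.
#' @export
ap_features <- function(sw, threshold_dvdt = 20) {
  stopifnot(inherits(sw, "sweep"))
  v <- sw$samples
  fs <- sw$sampling_rate
  tt <- sweep_times(sw)
  dvdt <- c(0, diff(v)) * fs / 1000 # mV/sample -> V/s
  cand <- which(dvdt >= threshold_dvdt & tt >= sw$stim_time)
  cand <- cand[cand > 1L]
  if (length(cand) == 0L) stop("no action potential found", call. = FALSE)
  i_thr <- cand[1L]
  # takeoff potential: the sample before the first suprathreshold upstroke
  thr <- v[i_thr - 1L]
  i_peak <- i_thr - 1L + which.max(v[i_thr:length(v)])
  amp <- v[i_peak] - thr
  if (amp <= 0) stop("no action potential found", call. = FALSE)
  half_level <- thr + amp / 2

  cross_time <- function(i, j) {
    # linear interpolation of the half-level crossing between samples i, j
    tt[i] + (half_level - v[i]) / (v[j] - v[i]) * (tt[j] - tt[i])
  }
  up <- which(v[i_thr:i_peak] >= half_level)[1L] + i_thr - 1L
  t_up <- if (up > 1L) cross_time(up - 1L, up) else tt[up]
  down_rel <- which(v[i_peak:length(v)] <= half_level)[1L]
  if (is.na(down_rel)) stop("action potential does not repolarize",
                            call. = FALSE)
  down <- down_rel + i_peak - 1L
  t_down <- cross_time(down - 1L, down)
  list(
    threshold_mv = thr,
    amplitude_mv = amp,
    half_width_s = t_down - t_up,
    decay_time_s = t_down - tt[i_peak]
  )
}

#' Rheobase from a family of current steps
#'
#' @param sweeps List of voltage [ephys_sweep()]s, one per injected current.
#' @param currents Injected currents in pA, same order as `sweeps` (must be
#'   monotone increasing).
#' @param threshold_dvdt dV/dt criterion in V/s used to detect an AP.
#' @return Smallest current (pA) eliciting at least one action potential, or
#'   `NA_real_` when no step does.
#' @export
rheobase <- function(sweeps, currents, threshold_dvdt = 20) {
  stopifnot(length(sweeps) == length(currents))
  if (is.unsorted(currents, strictly = TRUE)) {
    stop("`currents` must be strictly increasing", call. = FALSE)
  }
  for (i in seq_along(sweeps)) {
    has_ap <- !inherits(try(ap_features(sweeps[[i]], threshold_dvdt),
                            silent = TRUE), "try-error")
    if (has_ap) return(currents[i])
  }
  NA_real_
}
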