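test_that("event bursts follow the fixed-threshold rule", {
  # 5 events 50 ms apart qualify; duration is last minus first event
  r5 <- detect_event_bursts(seq(0, by = 0.05, length.out = 5), duration = 10)
  expect_identical(nrow(r5$bursts), 1L)
  expect_equal(r5$bursts$end - r5$bursts$start, 0.2)
  expect_equal(r5$mean_duration, 0.2)
  # 4 events never qualify
  r4 <- detect_event_bursts(seq(0, by = 0.05, length.out = 4), duration = 10)
  expect_identical(nrow(r4$bursts), 0L)
  expect_true(is.na(r4$mean_duration))
})

test_that("event-burst scan is equivalent to the spike-train burst scan", {
  set.seed(60)
  for (i in 1:50) {
    tr <- random_poisson_train(runif(1, 1, 15), 30)
    ev <- detect_event_bursts(tr$spike_times, 30)
    sp <- detect_bursts(tr, 0.1, burst_params())
    expect_equal(ev$bursts$start, sp$start)
    expect_equal(ev$bursts$end, sp$end)
    expect_equal(ev$bursts$n_events, sp$n_spikes)
  }
})

test_that("sweep averaging reduces noise like 1/sqrt(n)", {
  base <- simulate_evoked_pair(-50, 25, noise_sd = 0)$sweep_minus70
  # identical sweeps average to themselves
  expect_equal(average_sweeps(list(base, base, base))$samples, base$samples)
  # 30 noisy sweeps: residual SD ~ sigma/sqrt(30)
  set.seed(61)
  sigma <- 2
  noisy <- lapply(1:30, function(i) {
    s <- base
    s$samples <- s$samples + rnorm(length(s$samples), 0, sigma)
    s
  })
  avg <- average_sweeps(noisy, 30)
  resid <- avg$samples - base$samples
  expect_equal(sd(resid), sigma / sqrt(30), tolerance = 0.1)
  # too few sweeps or mismatched shapes are errors
  expect_error(average_sweeps(noisy[1:5], 30), "need 30")
  short <- ephys_sweep(base$samples[1:100], base$sampling_rate, 0.005)
  expect_error(average_sweeps(list(base, short)), "share")
})

test_that("NMDA/AMPA quantification is exact on constructed pairs", {
  pair <- simulate_evoked_pair(-50, 25, noise_sd = 0)
  q <- nmda_ampa_ratio(pair)
  expect_identical(q$ratio, 0.5)
  expect_true(q$qc_pass)
  # offset invariance: shifting both sweeps leaves the ratio unchanged
  off <- pair
  off$sweep_minus70$samples <- off$sweep_minus70$samples + 13.7
  off$sweep_plus40$samples <- off$sweep_plus40$samples - 4.2
  expect_equal(nmda_ampa_ratio(off)$ratio, 0.5, tolerance = 1e-12)
  # flat +40 sweep -> ratio 0
  flat <- simulate_evoked_pair(-50, 0, noise_sd = 0)
  expect_equal(nmda_ampa_ratio(flat)$ratio, 0)
  # small AMPA response fails QC
  weak <- simulate_evoked_pair(-10, 5, noise_sd = 0)
  expect_false(nmda_ampa_ratio(weak)$qc_pass)
})

test_that("ratio recovery is unbiased on 30-sweep averages", {
  set.seed(62)
  errs <- vapply(1:30, function(i) {
    ampa <- runif(1, -80, -40)
    nmda <- runif(1, 15, 40)
    pairs <- lapply(1:30, function(j) {
      simulate_evoked_pair(ampa, nmda, noise_sd = 2)
    })
    avg <- list(
      sweep_minus70 = average_sweeps(lapply(pairs, `[[`, "sweep_minus70")),
      sweep_plus40 = average_sweeps(lapply(pairs, `[[`, "sweep_plus40")),
      baseline_window = 0.05
    )
    got <- nmda_ampa_ratio(avg)$ratio
    (got - nmda / abs(ampa)) / (nmda / abs(ampa))
  }, 0)
  expect_lt(mean(abs(errs)), 0.05)
  expect_lt(abs(mean(errs)), 0.03) # near-zero bias
})

test_that("exponential decay fitting recovers tau", {
  # noiseless: within 1%
  sw <- simulate_evoked_pair(-50, 25, tau_decay = 0.08,
                             noise_sd = 0)$sweep_plus40
  expect_equal(fit_decay_tau(sw), 0.08, tolerance = 0.01)
  # sigma = 2 pA: within 10% over seeds
  set.seed(63)
  taus <- vapply(1:20, function(i) {
    s <- simulate_evoked_pair(-50, 25, tau_decay = 0.08,
                              noise_sd = 2)$sweep_plus40
    fit_decay_tau(s)
  }, 0)
  expect_lt(max(abs(taus - 0.08) / 0.08), 0.1)
  # flat trace cannot be fit
  flat <- ephys_sweep(numeric(5000), 10000, stim_time = 0.1)
  expect_error(fit_decay_tau(flat), "peak")
})

test_that("passive properties recover the RC ground truth", {
  # synthetic RC response: R = 150 MOhm, tau = 20 ms, -25 pA step
  fs <- 10000
  r_mohm <- 150
  tau <- 0.02
  i_pa <- -25
  dv <- i_pa * r_mohm / 1000 # mV
  tt <- (0:(fs - 1)) / fs
  v <- ifelse(tt >= 0.1 & tt < 0.6, dv * (1 - exp(-(tt - 0.1) / tau)), 0)
  v[tt >= 0.6] <- dv * exp(-(tt[tt >= 0.6] - 0.6) / tau)
  sw <- ephys_sweep(v - 65, fs, stim_time = 0.1) # resting at -65 mV
  pp <- passive_properties(sw, injected_current = i_pa)
  expect_equal(pp$rin_mohm, 150, tolerance = 0.02)
  expect_equal(pp$tau_s, 0.02, tolerance = 0.02)
  expect_true(pp$steady)
  # Ohm's law example: -2.5 mV at -25 pA is 100 MOhm
  v2 <- ifelse(tt >= 0.1 & tt < 0.6, -2.5 * (1 - exp(-(tt - 0.1) / 0.005)), 0)
  sw2 <- ephys_sweep(v2, fs, stim_time = 0.1)
  expect_equal(passive_properties(sw2, -25)$rin_mohm, 100, tolerance = 0.01)
  expect_error(passive_properties(sw, injected_current = 0), "non-zero")
})

# stylized AP waveform: resting -65 mV, fast depolarization from a known
# takeoff potential to a peak, then repolarization
synthetic_ap_sweep <- function(fs = 50000, takeoff = -40, peak = 30) {
  tt <- (0:(0.1 * fs - 1)) / fs
  v <- rep(-65, length(tt))
  ramp <- tt >= 0.02 & tt < 0.05 # slow depolarization, ~0.8 V/s
  v[ramp] <- -65 + (takeoff + 65) * (tt[ramp] - 0.02) / 0.03
  spike <- tt >= 0.05 & tt < 0.0506 # fast upstroke: >100 V/s
  v[spike] <- takeoff + (peak - takeoff) * (tt[spike] - 0.05) / 0.0006
  fall <- tt >= 0.0506 & tt < 0.054
  v[fall] <- peak - (peak + 65) * (tt[fall] - 0.0506) / 0.0034
  v[tt >= 0.054] <- -65
  ephys_sweep(v, fs, stim_time = 0.01)
}

test_that("AP features and rheobase come from the dV/dt criterion", {
  sw <- synthetic_ap_sweep()
  f <- ap_features(sw)
  expect_lt(abs(f$threshold_mv - (-40)), 1) # takeoff within 1 mV
  expect_equal(f$amplitude_mv, 30 - f$threshold_mv, tolerance = 0.5)
  expect_gt(f$half_width_s, 0)
  expect_gt(f$decay_time_s, 0)
  expect_lt(f$half_width_s, 0.005)

  flat <- ephys_sweep(rep(-65, 5000), 50000, stim_time = 0.01)
  expect_error(ap_features(flat), "no action potential")

  # ladder where APs start at 20 pA
  ladder <- list(flat, sw, sw)
  expect_equal(rheobase(ladder, c(10, 20, 30)), 20)
  expect_true(is.na(rheobase(list(flat, flat), c(10, 20))))
  expect_error(rheobase(list(flat, flat), c(20, 10)), "increasing")
})
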