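make_well <- function(rates, duration = 100) {
  trains <- lapply(seq_along(rates), function(i) {
    n <- round(rates[i] * duration)
    t <- if (n > 0) seq(0.5, duration - 0.5, length.out = n) else numeric(0)
    spike_train(t, duration, electrode_id = sprintf("E%02d", i))
  })
  well_recording(trains, n_electrodes = max(12L, length(rates)))
}

test_that("active-electrode selection uses the inclusive rate boundary", {
  w <- make_well(c(0.1, 0.05, 0, 2), duration = 1200)
  act <- active_electrodes(w, min_rate = 0.1)
  expect_setequal(act, c("E01", "E04"))
  # brute-force rate filter agrees on random wells
  set.seed(30)
  for (i in 1:10) {
    rates <- runif(12, 0, 0.4)
    w_i <- make_well(rates, duration = 100)
    brute <- sprintf("E%02d", which(round(rates * 100) / 100 >= 0.1))
    expect_setequal(active_electrodes(w_i, 0.1), brute)
  }
})

test_that("mean firing rate averages active channels only", {
  w <- make_well(c(1, 2, 3, 0.001), duration = 100)
  expect_equal(mean_firing_rate(w, c("E01", "E02", "E03")), 2)
  expect_equal(mean_firing_rate(w, "E02"), 2)
  expect_warning(mfr0 <- mean_firing_rate(w, character(0)), "no active")
  expect_true(is.na(mfr0))
})

test_that("network-burst participation is strictly greater than 80%", {
  # 10 active channels: bursts on 9 make a network burst, on 8 do not
  active <- sprintf("E%02d", 1:10)
  cb_at <- function(n_ch) {
    do.call(rbind, lapply(seq_len(n_ch), function(e) {
      data.frame(electrode_id = sprintf("E%02d", e),
                 start = c(10, 20), end = c(10.5, 20.5), n_spikes = 20L)
    }))
  }
  nb9 <- detect_network_bursts(cb_at(9L), active)
  expect_identical(nrow(nb9), 2L)
  expect_identical(nb9$n_channels, c(9L, 9L))
  nb8 <- detect_network_bursts(cb_at(8L), active)
  expect_identical(nrow(nb8), 0L)
  # < 2 active channels: empty result with warning
  expect_warning(nb1 <- detect_network_bursts(cb_at(9L), "E01"), "active")
  expect_identical(nrow(nb1), 0L)
})

test_that("the full pipeline honors the participation boundary", {
  w9 <- synchronized_burst_well(n_active = 10L, n_bursting = 9L)
  m9 <- summarize_well(w9)
  expect_identical(m9$n_active, 10L)
  expect_gt(m9$nb_rate, 0)
  w8 <- synchronized_burst_well(n_active = 10L, n_bursting = 8L)
  m8 <- summarize_well(w8)
  expect_identical(m8$nb_rate, 0)
})

test_that("channel bursts merge transitively across small gaps", {
  active <- sprintf("E%02d", 1:10)
  # chained bursts, each within 0.1 s of the previous, spread over channels
  cb <- do.call(rbind, lapply(1:9, function(e) {
    data.frame(electrode_id = sprintf("E%02d", e),
               start = 5 + 0.25 * (e - 1), end = 5.2 + 0.25 * (e - 1),
               n_spikes = 10L)
  }))
  nb <- detect_network_bursts(cb, active)
  expect_identical(nrow(nb), 1L)
  expect_equal(nb$start, 5)
  expect_equal(nb$end, 5.2 + 0.25 * 8)
  expect_identical(nb$n_spikes, 90L)
  # count never increases as the participation requirement rises
  n_by_p <- vapply(c(0.5, 0.7, 0.8, 0.85, 0.95), function(p) {
    nrow(detect_network_bursts(cb, active, participation = p))
  }, 0L)
  expect_true(all(diff(n_by_p) <= 0L))
})

test_that("network bursts recover the simulated ground truth", {
  cfg <- simulation_config(duration = 600, mean_nibi = 12, mean_nbd = 1.5,
                           participation_p = 1, background_rate = 0,
                           seed = 31L)
  sim <- simulate_well(cfg)
  m <- summarize_well(sim$well)
  active <- active_electrodes(sim$well)
  cb <- do.call(rbind, lapply(sim$well$trains[active], train_bursts))
  nbs <- detect_network_bursts(cb, active)
  expect_identical(nrow(nbs), length(sim$truth$nb_onsets))
  expect_lt(max(abs(nbs$start - sim$truth$nb_onsets)), 0.05)
})

test_that("NB statistics, NIBI and CV follow their definitions", {
  nbs <- data.frame(start = c(0, 10, 20), end = c(1, 11, 21),
                    n_channels = 10L, n_spikes = 100L)
  st <- network_burst_stats(nbs, duration = 1200)
  expect_equal(st$nb_rate, 3 * 60 / 1200)
  expect_equal(st$nibi, c(9, 9))
  expect_equal(st$mean_nibi, 9)
  expect_equal(st$mean_nbd, 1)
  expect_identical(sum(st$nbd_hist$counts), 3L)
  expect_identical(sum(st$nibi_hist$counts), 2L)
  # 40 network bursts in 20 min -> 2 per minute
  nbs40 <- data.frame(start = seq(0, by = 30, length.out = 40),
                      end = seq(1, by = 30, length.out = 40))
  expect_equal(network_burst_stats(nbs40, 1200)$nb_rate, 2)

  # CV: periodic -> 0; gamma shape 4 -> 0.5 within 10%
  expect_identical(cv_nibi(c(9, 9)), 0)
  expect_identical(cv_nibi(rep(2.5, 50)), 0)
  set.seed(32)
  g <- rgamma(500, shape = 4, scale = 2)
  expect_equal(cv_nibi(g), 0.5, tolerance = 0.1)
  expect_true(is.na(cv_nibi(numeric(0))))
  expect_true(is.na(cv_nibi(5)))
})

test_that("spikes inside plus outside network bursts is exactly conserved", {
  set.seed(33)
  sim <- simulate_well(control_preset(), seed = 33L)
  active <- active_electrodes(sim$well)
  cb <- do.call(rbind, lapply(sim$well$trains[active], train_bursts))
  nbs <- detect_network_bursts(cb, active)
  times <- sort(unlist(lapply(sim$well$trains[active],
                              function(tr) tr$spike_times)))
  inside_oracle <- brute_force_inside_count(times, nbs$start, nbs$end)
  pct <- pct_spikes_outside(sim$well, active, nbs)
  expect_identical(pct, 100 * (length(times) - inside_oracle) / length(times))

  # boundary cases
  expect_identical(pct_spikes_outside(sim$well, active, nbs[0, ]), 100)
})

test_that("pct_outside tracks the simulated background fraction", {
  cfg <- simulation_config(duration = 1200, mean_nibi = 10, mean_nbd = 1,
                           participation_p = 1, intra_burst_rate = 70,
                           background_rate = 3, seed = 34L)
  sim <- simulate_well(cfg)
  truth_frac <- 100 * mean(sim$truth$spikes$label == "background")
  m <- summarize_well(sim$well)
  # background spikes that land inside a burst window count as inside, so
  # the detected percentage sits a little below the labeled fraction
  expect_lt(abs(m$pct_outside - truth_frac), 5)
})

test_that("summarize_well is deterministic and complete on preset data", {
  sim <- simulate_well(control_preset(), seed = 35L)
  m1 <- summarize_well(sim$well)
  m2 <- summarize_well(sim$well)
  expect_identical(m1, m2)
  expect_true(all(is.finite(unlist(m1[c("mfr", "nb_rate", "mean_nbd",
                                        "mean_nibi", "cv_nibi",
                                        "pct_outside")]))))
  expect_gt(m1$nb_rate, 0)
})
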