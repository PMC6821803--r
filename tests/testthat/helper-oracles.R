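# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most literal possible algorithms.

# burst scan: walk the spike list one spike at a time
brute_force_bursts <- function(times, isi_threshold, min_spikes = 5L) {
  starts <- numeric(0)
  ends <- numeric(0)
  counts <- integer(0)
  run_start <- 1L
  n <- length(times)
  if (n == 0L) {
    return(data.frame(start = starts, end = ends, n_spikes = counts))
  }
  for (i in seq_len(n)) {
    end_of_run <- i == n || (times[i + 1L] - times[i]) > isi_threshold
    if (end_of_run) {
      len <- i - run_start + 1L
      if (len >= min_spikes) {
        starts <- c(starts, times[run_start])
        ends <- c(ends, times[i])
        counts <- c(counts, len)
      }
      run_start <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, n_spikes = counts)
}

# homogeneous Poisson spike train over [0, duration]
random_poisson_train <- function(rate, duration, electrode_id = "E01") {
  n <- rpois(1L, rate * duration)
  spike_train(unique(sort(runif(n, 0, duration))), duration, electrode_id)
}

# literal per-spike window membership count
brute_force_inside_count <- function(times, starts, ends) {
  inside <- 0L
  for (t in times) {
    for (k in seq_along(starts)) {
      if (t >= starts[k] && t <= ends[k]) {
        inside <- inside + 1L
        break
      }
    }
  }
  inside
}

# well with hand-placed synchronized bursts on `n_bursting` of `n_active`
# channels; every channel also gets slow pacemaker spikes so it counts as
# active without ever forming a burst (5 s ISI)
synchronized_burst_well <- function(n_active = 10L, n_bursting = 9L,
                                    n_events = 10L, duration = 600) {
  event_onsets <- seq(30, by = 50, length.out = n_events)
  trains <- lapply(seq_len(n_active), function(e) {
    keeper <- seq(2.5, duration - 5, by = 5) # 0.2 Hz background
    t <- keeper
    if (e <= n_bursting) {
      for (on in event_onsets) {
        t <- c(t, on + seq(0, by = 0.02, length.out = 8L))
      }
    }
    spike_train(sort(t), duration, electrode_id = sprintf("E%02d", e))
  })
  well_recording(trains, well_id = "Wsync", n_electrodes = max(12L, n_active))
}
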