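# Shared fixture builders: everything is generated in code at test time.

# A perfectly periodic bursting train: bursts every `period` seconds,
# `n_spk` spikes spaced `isi` apart, starting at `t0`.
periodic_train <- function(period, n_bursts, n_spk = 2, isi = 0.05,
                           neuron = "PD", temperature = 11, t0 = 0, ...) {
  onsets <- t0 + period * (seq_len(n_bursts) - 1)
  spikes <- as.vector(outer(isi * (seq_len(n_spk) - 1), onsets, "+"))
  spike_train(sort(spikes), neuron = neuron, temperature = temperature, ...)
}

# A random valid spike train (sorted unique uniform times).
random_train <- function(n, t_max = 100, neuron = "X", temperature = 11, ...) {
  spike_train(sort(runif(n, 0, t_max)), neuron = neuron,
              temperature = temperature, ...)
}

# Loop-based reference implementation of ISI burst partitioning, kept
# deliberately naive and independent of the vectorized detector.
oracle_bursts <- function(times, gap, min_spikes) {
  runs <- list()
  cur <- times[0]
  for (t in times) {
    if (length(cur) == 0 || t - cur[length(cur)] <= gap) {
      cur <- c(cur, t)
    } else {
      runs[[length(runs) + 1]] <- cur
      cur <- t
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  runs <- Filter(function(r) length(r) >= min_spikes, runs)
  data.frame(
    start = vapply(runs, min, numeric(1)),
    stop = vapply(runs, max, numeric(1)),
    n_spikes = vapply(runs, length, numeric(1))
  )
}

# Brute-force two-sample KS statistic: sup over the pooled sample points.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Deterministic-jitter generator config for construction tests.
noiseless_config <- function(...) {
  generator_config(period_jitter_cv = 0, lock_jitter_sd = 0,
                   uncoupled_period_cv = 0, ...)
}
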