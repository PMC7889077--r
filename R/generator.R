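#' Configuration for the synthetic spike-train generator
#'
#' Bundles every tunable of the generator, which emulates the statistical
#' structure the downstream analysis assumes: a fast pacemaker whose burst
#' period scales with temperature by a Q10, a slow unit whose bursts start a
#' fixed number of pacemaker cycles apart at a locked pacemaker phase
#' (integer coupling), and a slow unit of the same timescale with no
#' relationship to the pacemaker.
#'
#' @param reference_temperature Reference temperature in degrees Celsius
#'   (default 11).
#' @param pacemaker_period_ref Mean pacemaker burst period at the reference
#'   temperature, seconds (default 1.0).
#' @param pacemaker_q10 Factor by which pacemaker burst frequency increases
#'   per 10 degC (default 2.0, i.e. the period halves per 10 degC).
#' @param pacemaker_duty_cycle Fraction of each pacemaker cycle occupied by
#'   the burst, constant across temperature (default 0.3).
#' @param pacemaker_spikes_per_burst Spikes per pacemaker burst, >= 2
#'   (default 6), spread uniformly over the burst duration.
#' @param period_jitter_cv Coefficient of variation of the pacemaker cycle
#'   period; jitter is multiplicative log-normal so periods stay positive
#'   (default 0.02).
#' @param cycles_per_slow_burst Integer number k of pacemaker cycles per
#'   slow burst, either a single value or a range `c(k_min, k_max)` from
#'   which k is resampled per burst (default `c(5, 25)`).
#' @param lock_phase Pacemaker-cycle phase in `[0, 1)` at which the coupled
#'   slow unit's bursts start (default 0.5).
#' @param lock_jitter_sd SD of Gaussian jitter on the lock phase, in cycle
#'   units, wrapped mod 1 (default 0.02).
#' @param slow_burst_duration_frac Slow burst duration as a fraction of the
#'   slow period (default 0.4).
#' @param slow_intraburst_rate Within-burst firing rate of the slow units,
#'   Hz (default 20).
#' @param uncoupled_period_cv Coefficient of variation of the uncoupled slow
#'   unit's burst period (default 0.1).
#' @param slowdown_rate Fractional increase of the uncoupled unit's period
#'   per cycle, modelling slow non-stationarity of the rhythm (default 0).
#' @param seed Base integer seed; the three unit generators derive distinct
#'   sub-seeds from it so their randomness is independent.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(reference_temperature = 11,
                             pacemaker_period_ref = 1.0,
                             pacemaker_q10 = 2.0,
                             pacemaker_duty_cycle = 0.3,
                             pacemaker_spikes_per_burst = 6L,
                             period_jitter_cv = 0.02,
                             cycles_per_slow_burst = c(5L, 25L),
                             lock_phase = 0.5,
                             lock_jitter_sd = 0.02,
                             slow_burst_duration_frac = 0.4,
                             slow_intraburst_rate = 20,
                             uncoupled_period_cv = 0.1,
                             slowdown_rate = 0,
                             seed = 1L) {
  cfg <- list(
    reference_temperature = reference_temperature,
    pacemaker_period_ref = pacemaker_period_ref,
    pacemaker_q10 = pacemaker_q10,
    pacemaker_duty_cycle = pacemaker_duty_cycle,
    pacemaker_spikes_per_burst = as.integer(pacemaker_spikes_per_burst),
    period_jitter_cv = period_jitter_cv,
    cycles_per_slow_burst = as.integer(cycles_per_slow_burst),
    lock_phase = lock_phase,
    lock_jitter_sd = lock_jitter_sd,
    slow_burst_duration_frac = slow_burst_duration_frac,
    slow_intraburst_rate = slow_intraburst_rate,
    uncoupled_period_cv = uncoupled_period_cv,
    slowdown_rate = slowdown_rate,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$pacemaker_q10 > 0,
    cfg$pacemaker_period_ref > 0,
    cfg$pacemaker_duty_cycle > 0, cfg$pacemaker_duty_cycle < 1,
    cfg$pacemaker_spikes_per_burst >= 2,
    cfg$period_jitter_cv >= 0,
    all(cfg$cycles_per_slow_burst >= 1),
    length(cfg$cycles_per_slow_burst) %in% c(1L, 2L),
    cfg$lock_phase >= 0, cfg$lock_phase < 1,
    cfg$lock_jitter_sd >= 0,
    cfg$slow_burst_duration_frac > 0, cfg$slow_burst_duration_frac < 1,
    cfg$slow_intraburst_rate > 0,
    cfg$uncoupled_period_cv >= 0,
    cfg$slowdown_rate >= 0
  )
  structure(cfg, class = "generator_config")
}

#' Mean pacemaker period at a temperature under Q10 scaling
#'
#' `P(T) = P_ref * q10 ^ (-(T - T_ref) / 10)`: frequency increases by the
#' Q10 factor per 10 degC, so period shrinks by the same factor.
#'
#' @param cfg A [generator_config()].
#' @param temperature Temperature(s) in degrees Celsius.
#' @return Mean burst period(s) in seconds.
#' @export
thermal_period <- function(cfg, temperature) {
  cfg$pacemaker_period_ref *
    cfg$pacemaker_q10^(-(temperature - cfg$reference_temperature) / 10)
}

# log-normal multiplier with unit mean and the given CV
lognormal_jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

slow_k_values <- function(cfg) {
  k <- cfg$cycles_per_slow_burst
  if (length(k) == 1L) k else seq(k[1], k[2])
}

#' Generate a temperature-scaled pacemaker spike train
#'
#' Burst onsets form a renewal process whose mean period follows
#' [thermal_period()] at each protocol step, with multiplicative log-normal
#' period jitter of the configured CV. Each burst carries
#' `pacemaker_spikes_per_burst` spikes spread uniformly over
#' `duty_cycle * period`. One epoch (one `spike_train`) is emitted per
#' protocol step; spike times are relative to the epoch start.
#'
#' @param cfg A [generator_config()].
#' @param protocol A [temperature_protocol()].
#' @param preparation_id Preparation label for the emitted trains.
#' @param neuron Neuron label, default `"PD"`.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A `spike_trains` collection with an attribute `"bursts"`: a
#'   tibble of ground-truth burst onsets and drawn periods per epoch.
#' @export
generate_pacemaker <- function(cfg, protocol, preparation_id = "sim1",
                               neuron = "PD", seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(seed, {
    trains <- vector("list", nrow(protocol))
    truth <- vector("list", nrow(protocol))
    for (i in seq_len(nrow(protocol))) {
      temp <- protocol$temperature[i]
      dur <- protocol$duration[i]
      p_mean <- thermal_period(cfg, temp)
      if (dur < p_mean) {
        warning(sprintf("protocol step %d (%g degC) is shorter than one %.3g s period",
                        i, temp, p_mean), call. = FALSE)
      }
      n_max <- ceiling(dur / p_mean * 1.5) + 10L
      periods <- p_mean * lognormal_jitter(n_max, cfg$period_jitter_cv)
      onsets <- cumsum(c(0, periods[-n_max]))
      burst_dur <- cfg$pacemaker_duty_cycle * periods
      keep <- onsets + burst_dur <= dur
      onsets <- onsets[keep]
      periods <- periods[keep]
      burst_dur <- burst_dur[keep]
      spikes <- unlist(lapply(seq_along(onsets), function(j) {
        onsets[j] + seq(0, burst_dur[j],
                        length.out = cfg$pacemaker_spikes_per_burst)
      }))
      if (is.null(spikes)) spikes <- numeric(0)
      trains[[i]] <- spike_train(spikes, neuron = neuron, temperature = temp,
                                 preparation_id = preparation_id,
                                 epoch_id = protocol$epoch_id[i])
      truth[[i]] <- tibble::tibble(
        preparation_id = preparation_id,
        epoch_id = protocol$epoch_id[i],
        temperature = temp,
        onset = onsets,
        period = periods
      )
    }
    out <- spike_trains(trains)
    attr(out, "bursts") <- dplyr::bind_rows(truth)
    out
  })
}

# per-epoch ground-truth onsets from a generated pacemaker, or detected
# bursts from any other pacemaker train collection
pacemaker_onsets <- function(pacemaker) {
  gt <- attr(pacemaker, "bursts")
  if (!is.null(gt)) {
    return(split(gt, factor(gt$epoch_id, levels = unique(gt$epoch_id))))
  }
  if (inherits(pacemaker, "spike_train")) pacemaker <- spike_trains(pacemaker)
  seqs <- lapply(pacemaker, function(tr) {
    bs <- detect_bursts(tr)
    tibble::tibble(
      preparation_id = tr$preparation_id,
      epoch_id = tr$epoch_id,
      temperature = tr$temperature,
      onset = bs$bursts$start,
      period = bs$bursts$period
    )
  })
  names(seqs) <- vapply(pacemaker, function(tr) tr$epoch_id, character(1))
  seqs
}

#' Generate a slow unit integer-coupled to a pacemaker
#'
#' Each slow burst starts at pacemaker phase `lock_phase` (plus wrapped
#' Gaussian jitter) of a cycle exactly `k` cycles after the previous burst's
#' anchor cycle, with `k` resampled per burst from
#' `cfg$cycles_per_slow_burst`. The slow period is therefore built from
#' whole pacemaker cycles, which is the mechanism that guarantees integer
#' structure: the slow unit fires when periodic disinhibition timed by the
#' pacemaker allows it to.
#'
#' @param cfg A [generator_config()].
#' @param pacemaker The pacemaker as returned by [generate_pacemaker()] (its
#'   ground-truth onsets are used), or any `spike_trains` collection (bursts
#'   are then detected with default parameters).
#' @param neuron Neuron label, default `"LG"`.
#' @param seed Integer seed; defaults to `cfg$seed + 1L` so draws are
#'   independent of the pacemaker's.
#' @return A `spike_trains` collection (one train per pacemaker epoch) with
#'   attribute `"truth"`: a tibble of the sampled k sequence, anchor cycle
#'   indices, realized lock phases, burst starts and durations.
#' @export
generate_coupled_slow <- function(cfg, pacemaker, neuron = "LG",
                                  seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  epochs <- pacemaker_onsets(pacemaker)
  kvals <- slow_k_values(cfg)
  withr::with_seed(seed, {
    trains <- vector("list", length(epochs))
    truth <- vector("list", length(epochs))
    for (i in seq_along(epochs)) {
      ep <- epochs[[i]]
      onsets <- ep$onset
      periods <- ep$period
      m <- length(onsets)
      anchors <- integer(0)
      a <- 1L
      while (a <= m) {
        anchors <- c(anchors, a)
        a <- a + if (length(kvals) == 1L) kvals else sample(kvals, 1L)
      }
      # the last anchor has no following burst; k_j = anchor_{j+1} - anchor_j
      phases <- (cfg$lock_phase +
                   rnorm(length(anchors), 0, cfg$lock_jitter_sd)) %% 1
      starts <- onsets[anchors] + phases * periods[anchors]
      ks <- diff(anchors)
      durations <- cfg$slow_burst_duration_frac * ks * periods[anchors[-length(anchors)]]
      n_bursts <- length(ks)  # last anchor dropped: no defined slow period
      starts_b <- starts[seq_len(n_bursts)]
      if (n_bursts > 1 &&
          (is.unsorted(starts_b, strictly = TRUE) ||
           any(starts_b[-1] < starts_b[-n_bursts] + durations[-n_bursts]))) {
        stop("lock_jitter_sd too large: coupled slow bursts are not ",
             "monotonically ordered", call. = FALSE)
      }
      spikes <- unlist(lapply(seq_len(n_bursts), function(j) {
        n_spk <- max(2L, floor(durations[j] * cfg$slow_intraburst_rate) + 1L)
        starts_b[j] + seq(0, durations[j], length.out = n_spk)
      }))
      if (is.null(spikes)) spikes <- numeric(0)
      trains[[i]] <- spike_train(spikes, neuron = neuron,
                                 temperature = ep$temperature[1],
                                 preparation_id = ep$preparation_id[1],
                                 epoch_id = ep$epoch_id[1])
      truth[[i]] <- tibble::tibble(
        preparation_id = ep$preparation_id[1],
        epoch_id = ep$epoch_id[1],
        temperature = ep$temperature[1],
        k = ks,
        anchor_cycle = anchors[seq_len(n_bursts)],
        phase = phases[seq_len(n_bursts)],
        start = starts_b,
        duration = durations
      )
    }
    out <- spike_trains(trains)
    attr(out, "truth") <- dplyr::bind_rows(truth)
    out
  })
}

#' Generate a slow unit with no coupling to any pacemaker
#'
#' A renewal process with mean period `mean(k) * P(T)` — the same timescale
#' as the coupled unit — and period CV `uncoupled_period_cv`, independent of
#' any pacemaker. Serves as the null unit for coupling and phase statistics.
#'
#' @param cfg A [generator_config()].
#' @param protocol A [temperature_protocol()].
#' @param preparation_id Preparation label.
#' @param neuron Neuron label, default `"DG"`.
#' @param seed Integer seed; defaults to `cfg$seed + 2L`.
#' @return A `spike_trains` collection, one train per protocol step, with
#'   attribute `"bursts"` holding the ground-truth onsets and periods.
#' @export
generate_uncoupled_slow <- function(cfg, protocol, preparation_id = "sim1",
                                    neuron = "DG", seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "generator_config"))
  mean_k <- mean(slow_k_values(cfg))
  withr::with_seed(seed, {
    trains <- vector("list", nrow(protocol))
    truth <- vector("list", nrow(protocol))
    for (i in seq_len(nrow(protocol))) {
      temp <- protocol$temperature[i]
      dur <- protocol$duration[i]
      p_mean <- mean_k * thermal_period(cfg, temp)
      n_max <- ceiling(dur / p_mean * 2) + 10L
      periods <- p_mean * lognormal_jitter(n_max, cfg$uncoupled_period_cv)
      if (cfg$slowdown_rate > 0) {
        periods <- periods * (1 + cfg$slowdown_rate)^(seq_along(periods) - 1)
      }
      first <- runif(1) * p_mean
      onsets <- first + cumsum(c(0, periods[-n_max]))
      durations <- cfg$slow_burst_duration_frac * periods
      keep <- onsets + durations <= dur
      onsets <- onsets[keep]; periods <- periods[keep]
      durations <- durations[keep]
      spikes <- unlist(lapply(seq_along(onsets), function(j) {
        n_spk <- max(2L, floor(durations[j] * cfg$slow_intraburst_rate) + 1L)
        onsets[j] + seq(0, durations[j], length.out = n_spk)
      }))
      if (is.null(spikes)) spikes <- numeric(0)
      trains[[i]] <- spike_train(spikes, neuron = neuron, temperature = temp,
                                 preparation_id = preparation_id,
                                 epoch_id = protocol$epoch_id[i])
      truth[[i]] <- tibble::tibble(
        preparation_id = preparation_id,
        epoch_id = protocol$epoch_id[i],
        temperature = temp,
        onset = onsets,
        period = periods
      )
    }
    out <- spike_trains(trains)
    attr(out, "bursts") <- dplyr::bind_rows(truth)
    out
  })
}

#' Generate a full synthetic recording (pacemaker + coupled + uncoupled)
#'
#' Convenience wrapper producing the three units of one preparation over a
#' temperature protocol, with ground truth attached.
#'
#' @inheritParams generate_pacemaker
#' @param labels Named character vector with entries `pacemaker`, `coupled`
#'   and `uncoupled` giving the neuron labels to emit.
#' @return A `spike_trains` collection containing all three units, with
#'   attributes `"pacemaker_bursts"`, `"coupled_truth"` and
#'   `"uncoupled_bursts"`.
#' @export
generate_recording <- function(cfg, protocol, preparation_id = "sim1",
                               seed = cfg$seed,
                               labels = c(pacemaker = "PD", coupled = "LG",
                                          uncoupled = "DG")) {
  pd <- generate_pacemaker(cfg, protocol, preparation_id,
                           neuron = labels[["pacemaker"]], seed = seed)
  lg <- generate_coupled_slow(cfg, pd, neuron = labels[["coupled"]],
                              seed = seed + 1L)
  dg <- generate_uncoupled_slow(cfg, protocol, preparation_id,
                                neuron = labels[["uncoupled"]],
                                seed = seed + 2L)
  out <- spike_trains(c(unclass(pd), unclass(lg), unclass(dg)))
  attr(out, "pacemaker_bursts") <- attr(pd, "bursts")
  attr(out, "coupled_truth") <- attr(lg, "truth")
  attr(out, "uncoupled_bursts") <- attr(dg, "bursts")
  out
}
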