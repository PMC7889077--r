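test_that("phase increases linearly over the fast cycle", {
  # fast bursts start at 0 and 1.2
  fast <- detect_bursts(spike_train(c(0, 0.05, 1.2, 1.25), "PD", 11),
                        gap_threshold = 0.2, min_spikes = 2)
  expect_equal(phase_at(0, fast), 0)
  expect_equal(phase_at(0.6, fast), 0.5)
  expect_equal(phase_at(0.3, fast), 0.25)
  expect_true(is.na(phase_at(1.2, fast)))   # at/after last start: undefined
  expect_true(is.na(phase_at(-0.1, fast)))  # before first start
  expect_equal(phase_at(c(0, 0.3, 5), fast), c(0, 0.25, NA))
})

test_that("every fast burst start is at phase exactly 0", {
  fast <- detect_bursts(periodic_train(1.1, 20, neuron = "PD"))
  starts <- fast$bursts$start
  ph <- phase_at(starts, fast)
  expect_equal(ph[-length(ph)], rep(0, length(ph) - 1))
})

test_that("burst-start phases truncate to the first n and exclude short units", {
  fast <- detect_bursts(periodic_train(1, 520, neuron = "PD"))
  slow50 <- detect_bursts(periodic_train(10, 50, n_spk = 5, isi = 0.1,
                                         neuron = "LG", t0 = 0.5))
  samp <- burst_start_phases(slow50, fast, first_n = 40)
  expect_equal(samp$n, 40)
  expect_equal(samp$angles, rep(0.5, 40))

  slow39 <- detect_bursts(periodic_train(10, 39, n_spk = 5, isi = 0.1,
                                         neuron = "LG", t0 = 0.5))
  expect_message(out <- burst_start_phases(slow39, fast, first_n = 40),
                 "excluding")
  expect_null(out)
})

test_that("the coupled generator's lock phase is recovered exactly at zero jitter", {
  cfg <- noiseless_config(lock_phase = 0.3, seed = 6L)
  prot <- temperature_protocol(c(11, 19), 700)
  pd <- generate_pacemaker(cfg, prot)
  lg <- generate_coupled_slow(cfg, pd)
  seqs <- detect_bursts_all(spike_trains(c(unclass(pd), unclass(lg))))
  samp <- burst_start_phases(seqs[3:4], seqs[1:2], first_n = 40)
  st <- circular_stats(samp)
  expect_equal(st$mean_phase, 0.3, tolerance = 1e-9)
  expect_equal(st$circ_sd, 0, tolerance = 1e-6)
})

test_that("circular statistics match explicit vector sums", {
  st <- circular_stats(rep(0.2, 12))
  expect_equal(st$R, 1)
  expect_equal(st$mean_phase, 0.2)
  expect_equal(st$circ_sd, 0)

  # antipodal pair: resultant cancels, mean undefined
  st2 <- circular_stats(c(0.0, 0.5))
  expect_equal(st2$R, 0)
  expect_true(is.na(st2$mean_phase))

  # {0.1, 0.2, 0.3}: mean 0.2 by symmetry, R = (1 + 2 cos(0.2 pi)) / 3
  st3 <- circular_stats(c(0.1, 0.2, 0.3))
  expect_equal(st3$mean_phase, 0.2)
  expect_equal(st3$R, (1 + 2 * cos(0.2 * pi)) / 3)
  expect_equal(st3$circ_sd, sqrt(-2 * log(st3$R)) / (2 * pi))
})

test_that("the Rayleigh statistic is n R squared, identically", {
  rt <- rayleigh_test(rep(0.7, 30))
  expect_equal(rt$z, 30)
  expect_lt(rt$p, 1e-3)

  # an exact uniform grid of angles has zero resultant
  rt0 <- rayleigh_test((0:9) / 10)
  expect_equal(rt0$z, 0, tolerance = 1e-12)
  expect_equal(rt0$p, 1)

  withr::local_seed(51)
  for (rep in 1:20) {
    a <- runif(sample(2:50, 1))
    rt <- rayleigh_test(a)
    cs <- circular_stats(a)
    expect_equal(rt$z, cs$n * cs$R^2)
  }
  expect_error(rayleigh_test(0.3), "n >= 2")
})

test_that("small-sample Rayleigh p matches a Monte-Carlo null", {
  a <- c(0.05, 0.12, 0.18, 0.35, 0.52, 0.66, 0.80, 0.95)  # n = 8, mild
  rt <- rayleigh_test(a)
  withr::local_seed(52)
  z_null <- vapply(1:40000, function(i) rayleigh_test(runif(8))$z, numeric(1))
  expect_equal(rt$p, mean(z_null >= rt$z), tolerance = 0.02)
})

test_that("uncoupled-unit Rayleigh p values are calibrated across seeds", {
  withr::local_seed(53)
  prot <- temperature_protocol(11, 700)
  pvals <- vapply(1:100, function(s) {
    cfg <- generator_config(seed = 500L + s)
    pd <- generate_pacemaker(cfg, prot)
    dg <- generate_uncoupled_slow(cfg, prot)
    seqs <- detect_bursts_all(spike_trains(c(unclass(pd), unclass(dg))))
    samp <- suppressMessages(burst_start_phases(seqs[[2]], seqs[[1]],
                                                first_n = 40))
    rayleigh_test(samp)$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, qbinom(0.025, 100, 0.05) / 100)
  expect_lte(frac, qbinom(0.975, 100, 0.05) / 100)
})

test_that("rasters aligned to a locked unit superimpose across rows", {
  cfg <- noiseless_config(seed = 7L)
  prot <- temperature_protocol(11, 600)
  pd <- generate_pacemaker(cfg, prot)
  lg <- generate_coupled_slow(cfg, pd)
  fast_tr <- pd[[1]]
  seqs <- detect_bursts_all(spike_trains(c(unclass(pd), unclass(lg))))
  ras <- aligned_raster(seqs[[2]], fast_tr, seqs[[1]], window = 3)
  expect_gt(nrow(ras$rows), 0)
  # +/- 3 s at a 1 s fast period spans ~6 normalized periods
  expect_lte(max(abs(ras$rows$normalized_time)), 3.0 + 1e-9)
  # with perfect locking every row shows the same spike pattern mod 1
  frac_parts <- split(ras$rows$normalized_time %% 1, ras$rows$row)
  ref <- sort(unique(round(frac_parts[[1]], 6)))
  for (fp in frac_parts[-1]) {
    expect_equal(sort(unique(round(fp, 6))), ref)
  }
  expect_equal(sum(ras$histogram$probability), 1)
  expect_error(aligned_raster(seqs[[2]], fast_tr, seqs[[1]], window = -1),
               "window")
})

test_that("spike-phase histograms normalize and localize correctly", {
  fast <- detect_bursts(periodic_train(1, 60, neuron = "PD"))
  # slow spikes exactly at each fast-cycle midpoint
  slow_tr <- spike_train(0.5 + 0:49, "LG", 11)
  spp <- spike_phase_probability(slow_tr, fast, n_bins = 20)
  expect_equal(sum(spp$histogram$probability), 1)
  expect_equal(max(spp$histogram$probability), 1)
  expect_equal(spp$histogram$bin_mid[which.max(spp$histogram$probability)],
               0.525)
  expect_equal(unname(spp$burst_extent["onset"]), 0)

  # uniformly spread spikes: no bin wildly over-occupied
  withr::local_seed(54)
  slow_u <- spike_train(sort(runif(4000, 0, 58)), "DG", 11)
  spp_u <- spike_phase_probability(slow_u, fast, n_bins = 25)
  expect_lte(max(spp_u$histogram$probability), 2 / 25)

  empty <- spike_phase_probability(spike_train(numeric(0), "LG", 11), fast)
  expect_true(empty$empty)
  expect_error(spike_phase_probability(slow_tr, fast, n_bins = 1), "n_bins")
})
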