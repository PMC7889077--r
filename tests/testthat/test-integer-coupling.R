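test_that("significands are the fractional part of the period ratio", {
  expect_equal(significand(c(10, 10.1, 9.9, 5.25)),
               c(0, 0.1, 0.9, 0.25), tolerance = 1e-9)
  expect_error(significand(-1), "positive")
})

test_that("period pairing recovers hand-built ratios and significands", {
  fast <- detect_bursts(periodic_train(1, 35, neuron = "PD"))
  # slow bursts at 0, 10.1, 20.2, 30.3: periods 10.1 s over mean PD period 1
  slow_tr <- spike_train(
    as.vector(outer(seq(0, 0.4, by = 0.1), c(0, 10.1, 20.2, 30.3), "+")),
    "LG", 11)
  slow <- detect_bursts(slow_tr)
  pairs <- pair_periods(slow, fast)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$fast_period_mean, rep(1, 3))
  expect_equal(pairs$ratio, rep(10.1, 3))
  expect_equal(pairs$significand, rep(0.1, 3), tolerance = 1e-9)

  # slow period 9.9 s -> significand 0.9
  slow2 <- detect_bursts(spike_train(
    as.vector(outer(seq(0, 0.4, by = 0.1), c(0, 9.9, 19.8), "+")), "LG", 11))
  pairs2 <- pair_periods(slow2, fast)
  expect_equal(pairs2$significand, rep(0.9, 2), tolerance = 1e-9)

  # exactly 10 fast periods per slow period -> significand 0
  slow3 <- detect_bursts(spike_train(
    as.vector(outer(seq(0, 0.4, by = 0.1), c(0, 10, 20, 30), "+")), "LG", 11))
  pairs3 <- pair_periods(slow3, fast)
  expect_equal(pairs3$ratio, rep(10, 3))
  expect_equal(pairs3$significand, rep(0, 3))
})

test_that("slow bursts with no qualifying fast burst are dropped with a message", {
  fast <- detect_bursts(periodic_train(1, 12, neuron = "PD"))
  # second slow period [12, 22) lies beyond the last defined fast period
  slow <- detect_bursts(spike_train(
    as.vector(outer(seq(0, 0.4, by = 0.1), c(0, 12, 22), "+")), "LG", 11))
  expect_message(pairs <- pair_periods(slow, fast), "dropped 1")
  expect_equal(nrow(pairs), 1)
})

test_that("the empirical significand c.d.f. is the expected staircase", {
  cdf <- significand_cdf(rep(0.5, 10), n_boot = 10, seed = 1)
  expect_equal(cdf$F[cdf$grid < 0.5], rep(0, sum(cdf$grid < 0.5)))
  expect_equal(cdf$F[cdf$grid >= 0.5], rep(1, sum(cdf$grid >= 0.5)))

  n <- 20
  cdf2 <- significand_cdf((1:n) / n - 1 / (2 * n), n_boot = 10, seed = 1)
  expect_lt(max(abs(cdf2$F - cdf2$grid)), 1 / n + 1e-12)
  # band contains the point estimate pointwise
  expect_true(all(cdf2$lower <= cdf2$F & cdf2$F <= cdf2$upper))
  expect_error(significand_cdf(0.3), "at least 2")
  expect_error(significand_cdf(c(0.1, 0.2), n_boot = 0), "n_boot")
})

test_that("the bootstrap band covers the true uniform c.d.f. pointwise", {
  withr::local_seed(31)
  coverage <- vapply(1:15, function(rep) {
    x <- runif(100)
    cdf <- significand_cdf(x, n_boot = 300)
    mean(cdf$lower <= cdf$grid & cdf$grid <= cdf$upper)
  }, numeric(1))
  expect_gte(mean(coverage), 0.90)
})

test_that("the coupling area has its analytic extremes", {
  # perfect integer coupling: symmetric clustering at 0 and just below 1
  sig <- c(rep(0, 500), rep(1 - 1e-9, 500))
  expect_equal(coupling_area(sig), 0.25, tolerance = 1e-6)
  # one-sided clustering at 0 exceeds 0.25 under the unsigned definition
  expect_equal(coupling_area(rep(0, 7)), 0.5)
  # the midpoint grid {(i-1/2)/n}: two edge triangles of 1/(8n^2) plus
  # (n-1) interior segments of 1/(4n^2) -> total 1/(4n), vanishing with n
  n <- 50
  expect_equal(coupling_area((1:n) / n - 1 / (2 * n)), 1 / (4 * n),
               tolerance = 1e-12)
})

test_that("the staircase integral matches numeric integration", {
  withr::local_seed(32)
  grid <- seq(0, 1, length.out = 200001)
  for (rep in 1:10) {
    x <- runif(sample(2:40, 1))^sample(1:3, 1)
    want <- mean(abs(findInterval(grid, sort(x)) / length(x) - grid))
    got <- coupling_area(x)
    expect_equal(got, want, tolerance = 1e-4)
    expect_lte(got, 0.5)
  }
})

test_that("shuffling preserves the area for independent pairs", {
  withr::local_seed(33)
  pairs <- tibble::tibble(slow_period = runif(80, 8, 20),
                          fast_period_mean = runif(80, 0.9, 1.1))
  pairs$ratio <- pairs$slow_period / pairs$fast_period_mean
  pairs$significand <- significand(pairs$ratio)
  null <- shuffle_null(pairs, n_shuffle = 500, seed = 1)
  obs <- coupling_area(pairs$significand)
  expect_lt(abs(obs - mean(null$areas)), 3 * sd(null$areas))
  expect_gte(obs, quantile(null$areas, 0.025))
  expect_lte(obs, quantile(null$areas, 0.975))
  expect_length(null$significands, nrow(pairs))
})

test_that("a perfectly coupled unit exceeds every shuffled-null area", {
  # zero lock jitter but default period jitter: with a jitter-free pacemaker
  # every fast period is identical and shuffling cannot break integer ratios
  cfg <- generator_config(lock_jitter_sd = 0, seed = 2L)
  prot <- temperature_protocol(11, 2000)
  pd <- generate_pacemaker(cfg, prot)
  lg <- generate_coupled_slow(cfg, pd)
  seqs <- detect_bursts_all(spike_trains(c(unclass(pd), unclass(lg))))
  pairs <- pair_periods(seqs[[2]], seqs[[1]])
  null <- shuffle_null(pairs, n_shuffle = 1000, seed = 3)
  expect_gt(coupling_area(pairs$significand), max(null$areas))
  expect_error(shuffle_null(pairs, n_shuffle = 0), "n_shuffle")
})

test_that("the KS statistic matches a brute-force sup over thresholds", {
  expect_equal(ks_integer_coupling(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)),
               list(D = 0, p = 1))
  expect_equal(ks_integer_coupling(seq(0.01, 0.05, 0.01),
                                   seq(0.51, 0.55, 0.01))$D, 1)
  withr::local_seed(34)
  for (rep in 1:20) {
    x <- runif(sample(3:20, 1)); y <- runif(sample(3:20, 1))^2
    expect_equal(ks_integer_coupling(x, y)$D, oracle_ks_D(x, y))
  }
  expect_error(ks_integer_coupling(numeric(0), 0.5), "non-empty")
})

test_that("KS false-positive rate on uncoupled pairs is near nominal", {
  withr::local_seed(35)
  prot <- temperature_protocol(11, 700)
  hits <- vapply(1:50, function(s) {
    cfg <- generator_config(seed = 100L + s)
    pd <- generate_pacemaker(cfg, prot)
    dg <- generate_uncoupled_slow(cfg, prot)
    seqs <- detect_bursts_all(spike_trains(c(unclass(pd), unclass(dg))))
    pairs <- suppressMessages(pair_periods(seqs[[2]], seqs[[1]]))
    null <- shuffle_null(pairs, n_shuffle = 1, seed = s)
    ks_integer_coupling(pairs$significand, null$significands)$p < 0.05
  }, logical(1))
  expect_lte(sum(hits), qbinom(0.999, 50, 0.05))
})

test_that("the Bonferroni threshold is alpha over the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 9), 0.05 / 9)
  expect_equal(round(bonferroni_threshold(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "n_comparisons")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("ratio-temperature correlation uses midranks and flags degeneracy", {
  up <- tibble::tibble(temperature = c(7, 11, 15, 19),
                       ratio = c(5, 6, 7, 8))
  expect_equal(ratio_vs_temperature(up)$rho, 1)

  ties <- tibble::tibble(temperature = c(10, 10, 12, 12, 14, 14),
                         ratio = c(5.1, 5.3, 5.0, 5.6, 5.2, 5.4))
  # hand-computed Pearson correlation of the midranks:
  # temp ranks (1.5,1.5,3.5,3.5,5.5,5.5), ratio ranks (2,4,1,6,3,5)
  expect_equal(ratio_vs_temperature(ties)$rho, 4 / sqrt(16 * 17.5),
               tolerance = 1e-9)

  const <- tibble::tibble(temperature = c(7, 11, 15), ratio = rep(5, 3))
  expect_true(ratio_vs_temperature(const)$degenerate)
  expect_error(ratio_vs_temperature(up[1:2, ]), ">= 3 pairs")
})

test_that("temperature-independent ratios rarely test significant", {
  withr::local_seed(36)
  pvals <- vapply(1:50, function(rep) {
    pairs <- tibble::tibble(
      temperature = rep(c(7, 11, 15, 19, 23), each = 12),
      ratio = runif(60, 5, 25))
    ratio_vs_temperature(pairs)$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.85)
})

test_that("the per-temperature analysis separates coupled from uncoupled units", {
  cfg <- generator_config(seed = 9L)
  prot <- temperature_protocol(c(11, 19), 900)
  pd <- generate_pacemaker(cfg, prot)
  lg <- generate_coupled_slow(cfg, pd)
  dg <- generate_uncoupled_slow(cfg, prot)
  seqs <- detect_bursts_all(spike_trains(c(unclass(pd), unclass(lg),
                                           unclass(dg))))
  fast <- seqs[1:2]
  an_lg <- integer_coupling_analysis(
    suppressMessages(pair_periods_all(seqs[3:4], fast)),
    n_boot = 200, n_shuffle = 500, seed = 4)
  expect_true(all(vapply(an_lg, `[[`, logical(1), "significant")))
  an_dg <- integer_coupling_analysis(
    suppressMessages(pair_periods_all(seqs[5:6], fast)),
    n_boot = 200, n_shuffle = 500, seed = 5)
  expect_false(any(vapply(an_dg, `[[`, logical(1), "significant")))
  # area of the coupled unit clears the null band; uncoupled sits inside it
  r <- an_lg[[1]]
  expect_gt(r$area, quantile(r$null_areas, 0.975))
  r0 <- an_dg[[1]]
  expect_lt(r0$area, quantile(r0$null_areas, 0.999))
})
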