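#' Fractional part of a period ratio
#'
#' The significand, defined here as the value after the decimal point of
#' the slow-to-fast period ratio: `ratio - floor(ratio)`. Under integer
#' coupling significands cluster near 0 and 1; for a slow period of 10.1 s
#' over a mean fast period of 1 s the significand is 0.1, and for 9.9 s it
#' is 0.9.
#'
#' @param ratio Positive numeric vector of period ratios.
#' @return Values in `[0, 1)`.
#' @export
significand <- function(ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) stop("ratios must be positive",
                                          call. = FALSE)
  ratio - floor(ratio)
}

#' Pair each slow burst period with the mean fast period inside it
#'
#' For each slow burst i with a defined period, fast bursts whose start
#' lies in the half-open window `[start_i, start_{i+1})` and whose own
#' period is defined contribute to the mean fast period; the ratio of the
#' slow period to that mean and its [significand()] are recorded. Slow
#' bursts containing no qualifying fast burst are dropped with a message.
#'
#' @param slow,fast `burst_sequence` objects from the same preparation and
#'   epoch.
#' @return A tibble of period pairs: `slow_period`, `fast_period_mean`,
#'   `n_fast`, `ratio`, `significand`, plus identity columns.
#' @export
pair_periods <- function(slow, fast) {
  stopifnot(inherits(slow, "burst_sequence"), inherits(fast, "burst_sequence"))
  sb <- slow$bursts[!is.na(slow$bursts$period), , drop = FALSE]
  fb <- fast$bursts[!is.na(fast$bursts$period), , drop = FALSE]
  empty <- tibble::tibble(
    preparation_id = character(0), epoch_id = character(0),
    temperature = numeric(0), slow_start = numeric(0),
    slow_period = numeric(0), fast_period_mean = numeric(0),
    n_fast = integer(0), ratio = numeric(0), significand = numeric(0)
  )
  if (nrow(sb) == 0 || nrow(fb) == 0) {
    warning("no overlapping bursts between slow and fast sequences",
            call. = FALSE)
    return(empty)
  }
  # half-open windows [start_i, start_{i+1}); the slow start vector used for
  # binning includes the next start so the last defined period is bounded
  edges <- c(sb$start, sb$start[nrow(sb)] + sb$period[nrow(sb)])
  idx <- findInterval(fb$start, edges)
  ok <- idx >= 1 & idx <= nrow(sb) & fb$start < edges[pmin(idx + 1, length(edges))]
  means <- tapply(fb$period[ok], factor(idx[ok], levels = seq_len(nrow(sb))),
                  mean)
  n_fast <- tapply(rep(1L, sum(ok)), factor(idx[ok], levels = seq_len(nrow(sb))),
                   sum)
  have <- !is.na(means)
  n_dropped <- sum(!have)
  if (n_dropped > 0) {
    message(sprintf("pair_periods: dropped %d slow burst(s) with no qualifying fast burst (%s/%s)",
                    n_dropped, slow$preparation_id, slow$epoch_id))
  }
  if (!any(have)) return(empty)
  ratio <- sb$period[have] / as.numeric(means[have])
  tibble::tibble(
    preparation_id = slow$preparation_id,
    epoch_id = slow$epoch_id,
    temperature = slow$temperature,
    slow_start = sb$start[have],
    slow_period = sb$period[have],
    fast_period_mean = as.numeric(means[have]),
    n_fast = as.integer(n_fast[have]),
    ratio = ratio,
    significand = significand(ratio)
  )
}

#' Pair periods across matching epochs of two burst-sequence lists
#'
#' Matches slow and fast `burst_sequence`s by (preparation, epoch) and
#' row-binds the per-epoch [pair_periods()] tables.
#'
#' @param slow_seqs,fast_seqs Lists of `burst_sequence` objects.
#' @return A tibble of period pairs.
#' @export
pair_periods_all <- function(slow_seqs, fast_seqs) {
  key <- function(s) paste(s$preparation_id, s$epoch_id, sep = "\r")
  fast_by_key <- setNames(fast_seqs, vapply(fast_seqs, key, character(1)))
  out <- lapply(slow_seqs, function(s) {
    f <- fast_by_key[[key(s)]]
    if (is.null(f)) return(NULL)
    pair_periods(s, f)
  })
  dplyr::bind_rows(out)
}

#' Empirical c.d.f. of significands with a bootstrap confidence band
#'
#' The right-continuous empirical c.d.f. of the significand sample on
#' `[0, 1]`, with a pointwise percentile bootstrap band (resampling with
#' replacement) evaluated on a fixed grid. The band is widened, if needed,
#' to contain the point estimate pointwise.
#'
#' @param x Numeric significand sample in `[0, 1)`, or a period-pair tibble
#'   with a `significand` column.
#' @param n_boot Number of bootstrap resamples, default 1000.
#' @param level Band level, default 0.95.
#' @param seed Optional integer seed for reproducible resampling.
#' @param grid_n Number of grid points on `[0, 1]`, default 1001.
#' @return An object of class `significand_cdf` with elements
#'   `significands`, `grid`, `F`, `lower`, `upper`, `level`, `n_boot`, `n`.
#' @export
significand_cdf <- function(x, n_boot = 1000, level = 0.95, seed = NULL,
                            grid_n = 1001) {
  if (is.data.frame(x)) x <- x$significand
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 significands", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (any(x < 0 | x >= 1)) stop("significands must lie in [0, 1)", call. = FALSE)
  n <- length(x)
  grid <- seq(0, 1, length.out = grid_n)
  xs <- sort(x)
  F_hat <- findInterval(grid, xs) / n
  boot_fun <- function() {
    bm <- matrix(NA_real_, nrow = n_boot, ncol = grid_n)
    for (b in seq_len(n_boot)) {
      bm[b, ] <- findInterval(grid, sort(sample(x, n, replace = TRUE))) / n
    }
    bm
  }
  bm <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())
  alpha <- (1 - level) / 2
  lower <- apply(bm, 2, quantile, probs = alpha, names = FALSE)
  upper <- apply(bm, 2, quantile, probs = 1 - alpha, names = FALSE)
  structure(
    list(significands = xs, grid = grid, F = F_hat,
         lower = pmin(lower, F_hat), upper = pmax(upper, F_hat),
         level = level, n_boot = n_boot, n = n),
    class = "significand_cdf"
  )
}

#' @export
print.significand_cdf <- function(x, ...) {
  cat(sprintf("<significand_cdf> n = %d, %g%% bootstrap band (%d resamples); area = %.4f\n",
              x$n, 100 * x$level, x$n_boot, coupling_area(x)))
  invisible(x)
}

#' Area between a significand c.d.f. and the diagonal
#'
#' Computes the unsigned area `integral |F(x) - x| dx` over `[0, 1]`
#' exactly from the empirical staircase (piecewise closed form, no grid
#' approximation). Under perfect integer coupling (significands clustered
#' symmetrically at 0 and just below 1) the area is 0.25, the maximum the
#' extremal distributions bound; uniform significands give an area near 0.
#' Because the integrand is unsigned, one-sided clustering at 0 alone
#' scores 0.5, and symmetric clustering at 0.5 also scores 0.25 — a known
#' limitation of the metric.
#'
#' @param x A numeric significand sample in `[0, 1)` or a
#'   [significand_cdf()] object.
#' @return The area, a value in `[0, 0.5]`.
#' @export
coupling_area <- function(x) {
  if (inherits(x, "significand_cdf")) x <- x$significands
  x <- as.numeric(x)
  if (!length(x)) stop("empty significand sample", call. = FALSE)
  if (any(x < 0 | x >= 1)) stop("significands must lie in [0, 1)", call. = FALSE)
  u <- sort(unique(x))
  counts <- cumsum(tabulate(match(sort(x), u), nbins = length(u)))
  n <- length(x)
  # F = level[i] on [brk[i], brk[i+1])
  brk <- c(0, u, 1)
  level <- c(0, counts / n)
  seg <- function(a, b, c) {
    if (b <= a) return(0)
    if (c <= a) return(0.5 * ((b - c)^2 - (a - c)^2))
    if (c >= b) return(0.5 * ((c - a)^2 - (c - b)^2))
    0.5 * ((c - a)^2 + (b - c)^2)
  }
  total <- 0
  for (i in seq_along(level)) {
    total <- total + seg(brk[i], brk[i + 1], level[i])
  }
  total
}

#' Shuffled-period null for the coupling area and significand distribution
#'
#' Each shuffle independently permutes the slow-period list against the
#' fast-period-mean list, destroying any coupling while preserving both
#' marginals, then recomputes ratios, significands and the area. The first
#' shuffle's significands are returned as the designated null sample for
#' the two-sample KS comparison, keeping the test's sample sizes matched.
#'
#' @param pairs A period-pair tibble from [pair_periods()] (needs columns
#'   `slow_period` and `fast_period_mean`).
#' @param n_shuffle Number of shuffles, default 1000.
#' @param seed Optional integer seed.
#' @return An object of class `shuffle_null`: list with `areas` (length
#'   `n_shuffle`) and `significands` (the designated null sample).
#' @export
shuffle_null <- function(pairs, n_shuffle = 1000, seed = NULL) {
  if (nrow(pairs) < 2) stop("need at least 2 period pairs", call. = FALSE)
  if (n_shuffle < 1) stop("n_shuffle must be >= 1", call. = FALSE)
  slow <- pairs$slow_period
  fast <- pairs$fast_period_mean
  n <- length(slow)
  run <- function() {
    areas <- numeric(n_shuffle)
    first_sig <- NULL
    for (s in seq_len(n_shuffle)) {
      sig <- significand(slow[sample.int(n)] / fast)
      if (s == 1L) first_sig <- sig
      areas[s] <- coupling_area(sig)
    }
    list(areas = areas, significands = first_sig)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(out, list(n = n)), class = "shuffle_null")
}

#' Two-sample Kolmogorov-Smirnov test for integer coupling
#'
#' Compares observed significands against significands from shuffled
#' period pairings. A two-sample test is used rather than a one-sample test
#' against the uniform because significands of ratios of randomly paired
#' periods need not be exactly uniform for every combination of period
#' ranges.
#'
#' @param observed,null Non-empty numeric significand samples.
#' @return A list with the KS statistic `D = sup |F_obs - F_null|` and the
#'   asymptotic two-sided `p`.
#' @export
ks_integer_coupling <- function(observed, null) {
  if (!length(observed) || !length(null)) {
    stop("both significand samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(observed, null, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_comparisons Number of comparisons (e.g. temperature steps), >= 1.
#' @return `alpha / n_comparisons`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 9)  # 0.00556
bonferroni_threshold <- function(alpha, n_comparisons) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_comparisons < 1) stop("n_comparisons must be >= 1", call. = FALSE)
  alpha / n_comparisons
}

#' Spearman correlation of period ratio against temperature
#'
#' Tests whether the number of fast cycles per slow cycle trends with
#' temperature, pooling pairs across preparations. Ties (the discrete
#' temperature steps of the protocol) are handled by midranks.
#'
#' @param pairs A period-pair tibble with `ratio` and `temperature`
#'   columns; at least 3 pairs spanning at least 2 temperatures.
#' @return A list with `rho`, `p`, `n` and `degenerate` (TRUE when the
#'   ratios are constant and the correlation undefined).
#' @export
ratio_vs_temperature <- function(pairs) {
  if (nrow(pairs) < 3 || length(unique(pairs$temperature)) < 2) {
    stop("need >= 3 pairs spanning >= 2 temperatures", call. = FALSE)
  }
  if (length(unique(pairs$ratio)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = nrow(pairs),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(
    cor.test(pairs$ratio, pairs$temperature, method = "spearman",
             exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
       degenerate = FALSE)
}

#' Full per-temperature integer-coupling analysis
#'
#' Pools period pairs across preparations within each temperature and
#' computes, per temperature: the significand sample, its empirical c.d.f.
#' with bootstrap band, the coupling area, the shuffled-period null areas,
#' the two-sample KS statistic against the designated null sample, and a
#' significance flag at the Bonferroni-corrected level `alpha` divided by
#' the number of temperatures analysed.
#'
#' @param pairs A pooled period-pair tibble (see [pair_periods_all()]).
#' @param n_boot Bootstrap resamples for the c.d.f. band, default 1000.
#' @param n_shuffle Shuffles for the null, default 1000.
#' @param alpha Family-wise significance level, default 0.05.
#' @param seed Optional integer seed (per-temperature sub-seeds derived
#'   from it).
#' @return An object of class `coupling_analysis`: a named list (one entry
#'   per temperature) of `coupling_result` lists, with the ratio-trend test
#'   attached as attribute `"ratio_trend"`.
#' @export
integer_coupling_analysis <- function(pairs, n_boot = 1000, n_shuffle = 1000,
                                      alpha = 0.05, seed = NULL) {
  temps <- sort(unique(pairs$temperature))
  thr <- bonferroni_threshold(alpha, length(temps))
  results <- lapply(seq_along(temps), function(i) {
    pt <- pairs[pairs$temperature == temps[i], , drop = FALSE]
    sub_seed <- if (is.null(seed)) NULL else seed + i
    cdf <- significand_cdf(pt$significand, n_boot = n_boot, level = 0.95,
                           seed = sub_seed)
    null <- shuffle_null(pt, n_shuffle = n_shuffle,
                         seed = if (is.null(sub_seed)) NULL else sub_seed + 10000L)
    ks <- ks_integer_coupling(pt$significand, null$significands)
    structure(
      list(temperature = temps[i], n = nrow(pt),
           significands = pt$significand, cdf = cdf,
           area = coupling_area(pt$significand),
           null_areas = null$areas, null_significands = null$significands,
           D = ks$D, p = ks$p, threshold = thr,
           significant = is.finite(ks$p) && ks$p < thr),
      class = "coupling_result"
    )
  })
  names(results) <- sprintf("%g", temps)
  trend <- if (length(temps) >= 2 && nrow(pairs) >= 3) {
    ratio_vs_temperature(pairs)
  } else NULL
  structure(results, class = "coupling_analysis", ratio_trend = trend,
            alpha = alpha, threshold = thr)
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %g degC: n = %d, area = %.4f (null mean %.4f), D = %.3f, p = %.3g%s\n",
              x$temperature, x$n, x$area, mean(x$null_areas), x$D, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
print.coupling_analysis <- function(x, ...) {
  cat(sprintf("<coupling_analysis> %d temperature(s), threshold p < %.4g\n",
              length(x), attr(x, "threshold")))
  for (r in x) print(r)
  trend <- attr(x, "ratio_trend")
  if (!is.null(trend)) {
    cat(sprintf("ratio vs temperature: Spearman rho = %.3f, p = %.3g (n = %d)\n",
                trend$rho, trend$p, trend$n))
  }
  invisible(x)
}
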