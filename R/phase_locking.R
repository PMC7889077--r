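#' Phase of a time point within the fast-unit cycle
#'
#' Phase is assumed to increase uniformly and linearly over each fast
#' cycle: for `t` in `[start_k, start_{k+1})` the phase is
#' `(t - start_k) / period_k`, in cycle units `[0, 1)`. Times before the
#' first or at/after the last fast burst start have undefined phase and
#' return `NA`; callers must exclude them.
#'
#' @param t Numeric vector of times in seconds.
#' @param fast A `burst_sequence` of the fast unit.
#' @return Phases in `[0, 1)`, `NA` where undefined. Vectorized over `t`.
#' @export
#' @examples
#' # fast burst starts at 0 and 1.2: t = 0.3 is at phase 0.25
phase_at <- function(t, fast) {
  stopifnot(inherits(fast, "burst_sequence"))
  starts <- fast$bursts$start
  periods <- fast$bursts$period
  out <- rep(NA_real_, length(t))
  if (length(starts) < 2) return(out)
  k <- findInterval(t, starts)
  ok <- k >= 1 & k < length(starts) & !is.na(periods[pmax(k, 1)])
  out[ok] <- (t[ok] - starts[k[ok]]) / periods[k[ok]]
  out
}

#' Phases of the first n slow-unit burst starts in the fast cycle
#'
#' Collects the fast-cycle phases of slow burst starts, in chronological
#' order across the supplied epochs (all from one preparation and
#' temperature), and keeps the first `first_n` with defined phase. If fewer
#' than `first_n` qualifying burst starts exist the whole unit is excluded
#' (`NULL` is returned with a message): truncating every unit to the same
#' early-burst count avoids time-dependent confounds such as rhythm
#' slow-down, and units too short to reach the cap would otherwise be
#' over-weighted by their late bursts.
#'
#' @param slow,fast A `burst_sequence` or list of them (matched by epoch
#'   when lists).
#' @param first_n Number of burst starts to keep, default 40.
#' @return A `phase_sample` (list with `angles` in cycles and context
#'   fields), or `NULL` if the unit is excluded.
#' @export
burst_start_phases <- function(slow, fast, first_n = 40) {
  if (inherits(slow, "burst_sequence")) slow <- list(slow)
  if (inherits(fast, "burst_sequence")) fast <- list(fast)
  key <- function(s) paste(s$preparation_id, s$epoch_id, sep = "\r")
  fast_by_key <- setNames(fast, vapply(fast, key, character(1)))
  phases <- unlist(lapply(slow, function(s) {
    f <- fast_by_key[[key(s)]]
    if (is.null(f)) return(numeric(0))
    ph <- phase_at(s$bursts$start, f)
    ph[!is.na(ph)]
  }))
  if (is.null(phases)) phases <- numeric(0)
  s1 <- slow[[1]]
  if (length(phases) < first_n) {
    message(sprintf("excluding %s/%s @ %g degC: only %d of %d required burst starts",
                    s1$preparation_id, s1$neuron, s1$temperature,
                    length(phases), first_n))
    return(NULL)
  }
  phase_sample(head(phases, first_n),
               preparation_id = s1$preparation_id,
               neuron = s1$neuron, fast_neuron = fast[[1]]$neuron,
               temperature = s1$temperature)
}

#' Sample of circular phases in cycle units
#'
#' @param angles Numeric vector of phases in `[0, 1)` cycles.
#' @param preparation_id,neuron,fast_neuron,temperature Optional context.
#' @return An object of class `phase_sample`.
#' @export
phase_sample <- function(angles, preparation_id = NA_character_,
                         neuron = NA_character_, fast_neuron = NA_character_,
                         temperature = NA_real_) {
  angles <- as.numeric(angles)
  if (any(angles < 0 | angles >= 1)) {
    stop("phases must lie in [0, 1) cycles", call. = FALSE)
  }
  structure(list(angles = angles, preparation_id = preparation_id,
                 neuron = neuron, fast_neuron = fast_neuron,
                 temperature = temperature, n = length(angles)),
            class = "phase_sample")
}

#' @export
print.phase_sample <- function(x, ...) {
  cat(sprintf("<phase_sample> %s in %s cycle, %s @ %s degC: n = %d\n",
              x$neuron, x$fast_neuron, x$preparation_id,
              format(x$temperature), x$n))
  invisible(x)
}

as_phase_angles <- function(sample) {
  if (inherits(sample, "phase_sample")) sample$angles else as.numeric(sample)
}

#' Circular mean, resultant length and circular standard deviation
#'
#' Angles in cycle units are mapped to radians, summed as unit vectors, and
#' summarized by the mean direction (back in cycles), the mean resultant
#' length `R` in `[0, 1]` and the circular standard deviation
#' `sqrt(-2 log R)` converted to cycles. When `R` is numerically zero
#' (e.g. antipodal angles) the mean is undefined and flagged `NA`.
#'
#' @param sample A [phase_sample()] or numeric vector of phases in cycles.
#' @return A list with `mean_phase` (cycles), `R`, `circ_sd` (cycles), `n`.
#' @export
circular_stats <- function(sample) {
  a <- as_phase_angles(sample)
  n <- length(a)
  if (n < 1) stop("need at least 1 angle", call. = FALSE)
  theta <- 2 * pi * a
  C <- sum(cos(theta)); S <- sum(sin(theta))
  R <- sqrt(C^2 + S^2) / n
  if (R < 1e-12) {
    return(list(mean_phase = NA_real_, R = 0, circ_sd = Inf, n = n))
  }
  mean_phase <- (atan2(S, C) / (2 * pi)) %% 1
  circ_sd <- sqrt(-2 * log(R)) / (2 * pi)
  list(mean_phase = mean_phase, R = R, circ_sd = circ_sd, n = n)
}

#' Rayleigh test for non-uniformity of circular phases
#'
#' The statistic is `z = n * R^2` with `R` the mean resultant length; the
#' p value uses the standard small-sample-corrected closed form
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with `Rn = n * R`,
#' as in the classical circular-statistics toolboxes.
#'
#' @param sample A [phase_sample()] or numeric vector of phases in cycles.
#' @return A list with `z`, `p`, `R`, `n`.
#' @export
rayleigh_test <- function(sample) {
  a <- as_phase_angles(sample)
  n <- length(a)
  if (n < 2) stop("Rayleigh test needs n >= 2", call. = FALSE)
  cs <- circular_stats(a)
  Rn <- n * cs$R
  z <- Rn^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(z = z, p = min(p, 1), R = cs$R, n = n)
}

#' Combined circular summary and Rayleigh test
#'
#' @param sample A [phase_sample()] or numeric vector of phases in cycles.
#' @return A list of class `phase_stats` merging [circular_stats()] and
#'   [rayleigh_test()] output, plus the sample's context if available.
#' @export
phase_stats <- function(sample) {
  cs <- circular_stats(sample)
  rt <- rayleigh_test(sample)
  ctx <- if (inherits(sample, "phase_sample")) {
    sample[c("preparation_id", "neuron", "fast_neuron", "temperature")]
  } else list()
  structure(c(cs, rt[c("z", "p")], ctx), class = "phase_stats")
}

#' @export
print.phase_stats <- function(x, ...) {
  cat(sprintf("<phase_stats> n = %d: mean phase %.3f, R = %.3f, circ sd %.3f, Rayleigh z = %.2f, p = %.3g\n",
              x$n, x$mean_phase, x$R, x$circ_sd, x$z, x$p))
  invisible(x)
}

#' Fast-unit raster aligned to slow-unit burst starts
#'
#' One row per slow burst start: fast spikes within `+/- window` seconds of
#' the start, with time re-expressed in units of the mean fast burst period
#' computed from the fast bursts whose starts fall inside that same window
#' (window edges inclusive). Rows with no in-window fast burst of defined
#' period are dropped with a message. A column histogram of spike counts
#' per normalized-time bin is attached, normalized to sum to 1.
#'
#' @param slow A `burst_sequence` of the slow unit.
#' @param fast_train The fast unit's [spike_train()].
#' @param fast A `burst_sequence` detected from `fast_train`.
#' @param window Half-width of the alignment window in seconds, default 3.
#' @param n_bins Number of histogram bins, default 50.
#' @return An object of class `aligned_raster`: list with `rows` (tibble of
#'   `row`, `slow_start`, `normalization`, `normalized_time`), `histogram`
#'   (tibble of `bin_mid`, `count`, `probability`), `n_dropped`.
#' @export
aligned_raster <- function(slow, fast_train, fast, window = 3.0,
                           n_bins = 50) {
  stopifnot(inherits(slow, "burst_sequence"),
            inherits(fast_train, "spike_train"),
            inherits(fast, "burst_sequence"))
  if (window <= 0) stop("window must be positive", call. = FALSE)
  spikes <- fast_train$spike_times
  fstart <- fast$bursts$start
  fperiod <- fast$bursts$period
  rows <- list(); dropped <- 0L; row_i <- 0L
  for (s in slow$bursts$start) {
    inwin <- fstart >= s - window & fstart <= s + window & !is.na(fperiod)
    if (!any(inwin)) { dropped <- dropped + 1L; next }
    norm <- mean(fperiod[inwin])
    rel <- spikes[spikes >= s - window & spikes <= s + window] - s
    row_i <- row_i + 1L
    rows[[row_i]] <- tibble::tibble(
      row = row_i, slow_start = s, normalization = norm,
      normalized_time = rel / norm
    )
  }
  if (dropped > 0) {
    message(sprintf("aligned_raster: dropped %d row(s) with no in-window fast burst",
                    dropped))
  }
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows)) {
    extent <- max(abs(rows$normalized_time))
    breaks <- seq(-extent, extent, length.out = n_bins + 1)
    counts <- tabulate(findInterval(rows$normalized_time, breaks,
                                    rightmost.closed = TRUE), nbins = n_bins)
    hist <- tibble::tibble(
      bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      count = counts,
      probability = counts / sum(counts)
    )
  } else {
    hist <- tibble::tibble(bin_mid = numeric(0), count = integer(0),
                           probability = numeric(0))
  }
  structure(list(rows = rows, histogram = hist, n_dropped = dropped,
                 window = window, slow_neuron = slow$neuron,
                 fast_neuron = fast$neuron),
            class = "aligned_raster")
}

#' @export
print.aligned_raster <- function(x, ...) {
  cat(sprintf("<aligned_raster> %s spikes aligned to %s burst starts: %d rows (%d dropped), +/- %g s\n",
              x$fast_neuron, x$slow_neuron,
              if (nrow(x$rows)) max(x$rows$row) else 0L, x$n_dropped,
              x$window))
  invisible(x)
}

#' Slow-unit spike probability as a function of fast-cycle phase
#'
#' Histograms the fast-cycle phases of all slow-unit spikes with defined
#' phase over `[0, 1)`, normalized to sum to 1, and annotates the mean
#' fast-burst extent in phase: onset is 0 by construction and offset is
#' the mean fast duty cycle.
#'
#' @param slow_train The slow unit's [spike_train()].
#' @param fast A `burst_sequence` of the fast unit.
#' @param n_bins Number of phase bins, default 25 (>= 2).
#' @return A list with `histogram` (tibble `bin_mid`, `count`,
#'   `probability`), `n_spikes`, `n_excluded`, `burst_extent`
#'   (`c(onset, offset)` phases), `empty` flag.
#' @export
spike_phase_probability <- function(slow_train, fast, n_bins = 25) {
  stopifnot(inherits(slow_train, "spike_train"),
            inherits(fast, "burst_sequence"))
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  ph <- phase_at(slow_train$spike_times, fast)
  n_excluded <- sum(is.na(ph))
  ph <- ph[!is.na(ph)]
  # phases can marginally reach 1 when a spike's cycle runs long; wrap
  ph <- ph %% 1
  breaks <- seq(0, 1, length.out = n_bins + 1)
  if (!length(ph)) {
    return(list(histogram = tibble::tibble(
      bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      count = rep(0L, n_bins), probability = rep(NA_real_, n_bins)),
      n_spikes = 0L, n_excluded = n_excluded,
      burst_extent = c(onset = 0, offset = NA_real_), empty = TRUE))
  }
  counts <- tabulate(findInterval(ph, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  list(
    histogram = tibble::tibble(
      bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      count = counts, probability = counts / sum(counts)
    ),
    n_spikes = length(ph), n_excluded = n_excluded,
    burst_extent = c(onset = 0,
                     offset = mean(fast$bursts$duty_cycle, na.rm = TRUE)),
    empty = FALSE
  )
}
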