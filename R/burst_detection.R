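#' Default ISI burst-detection parameters by neuron label
#'
#' Slow gastric-mill-timescale units (LG, DG and any unrecognized label) use
#' a 1 s inter-spike-interval gap and at least 5 spikes per burst. Fast
#' pacemaker units (PD, AB) use at least 2 spikes and a 0.2 s gap: the
#' pacemaker's full period is about 1 s at 11 degC, so a 1 s gap would merge
#' consecutive bursts. The pacemaker gap is a per-neuron configuration
#' parameter and should be revisited if your fast unit's period differs
#' substantially from ~1 s.
#'
#' @param neuron Neuron label.
#' @return A list with elements `gap_threshold` (s) and `min_spikes`.
#' @export
default_burst_params <- function(neuron) {
  if (toupper(neuron) %in% c("PD", "AB", "PACEMAKER")) {
    list(gap_threshold = 0.2, min_spikes = 2L)
  } else {
    list(gap_threshold = 1.0, min_spikes = 5L)
  }
}

#' Detect bursts in a spike train by ISI gap thresholding
#'
#' Spikes are partitioned into maximal runs whose internal inter-spike
#' intervals are all `<= gap_threshold` (an ISI strictly longer than the
#' gap separates bursts). Runs with fewer than `min_spikes` spikes are
#' discarded entirely; their spikes belong to no burst. The burst period is
#' start-to-start between consecutive retained bursts and is undefined
#' (`NA`) for the last burst; the duty cycle is duration / period.
#'
#' @param train A [spike_train()].
#' @param gap_threshold Maximum within-burst ISI in seconds; defaults to the
#'   per-neuron value from [default_burst_params()].
#' @param min_spikes Minimum spikes per retained burst; same default source.
#' @return A `burst_sequence`: a list with the train's identity fields, a
#'   tibble `bursts` (`start`, `stop`, `n_spikes`, `duration`, `period`,
#'   `duty_cycle`) and `n_discarded_spikes`.
#' @export
#' @examples
#' tr <- spike_train(c(0, 0.1, 0.2, 2.0, 2.1, 2.2, 2.3, 2.4), "LG", 11)
#' detect_bursts(tr, gap_threshold = 1, min_spikes = 5)
detect_bursts <- function(train, gap_threshold = NULL, min_spikes = NULL) {
  stopifnot(inherits(train, "spike_train"))
  defaults <- default_burst_params(train$neuron)
  if (is.null(gap_threshold)) gap_threshold <- defaults$gap_threshold
  if (is.null(min_spikes)) min_spikes <- defaults$min_spikes
  stopifnot(gap_threshold > 0, min_spikes >= 1)

  t <- train$spike_times
  if (length(t) == 0) {
    bursts <- tibble::tibble(start = numeric(0), stop = numeric(0),
                             n_spikes = integer(0), duration = numeric(0),
                             period = numeric(0), duty_cycle = numeric(0))
    return(new_burst_sequence(train, bursts, 0L, gap_threshold, min_spikes))
  }
  run_id <- cumsum(c(1L, as.integer(diff(t) > gap_threshold)))
  n_per_run <- tabulate(run_id)
  starts <- t[!duplicated(run_id)]
  stops <- t[!duplicated(run_id, fromLast = TRUE)]
  keep <- n_per_run >= min_spikes
  discarded <- sum(n_per_run[!keep])
  starts <- starts[keep]; stops <- stops[keep]
  n_spk <- n_per_run[keep]
  period <- c(diff(starts), NA_real_)
  duration <- stops - starts
  bursts <- tibble::tibble(
    start = starts, stop = stops, n_spikes = as.integer(n_spk),
    duration = duration, period = period, duty_cycle = duration / period
  )
  new_burst_sequence(train, bursts, as.integer(discarded),
                     gap_threshold, min_spikes)
}

new_burst_sequence <- function(train, bursts, n_discarded, gap, min_spikes) {
  structure(
    list(
      preparation_id = train$preparation_id,
      neuron = train$neuron,
      temperature = train$temperature,
      epoch_id = train$epoch_id,
      bursts = bursts,
      n_discarded_spikes = n_discarded,
      gap_threshold = gap,
      min_spikes = min_spikes,
      train = train
    ),
    class = "burst_sequence"
  )
}

#' @export
print.burst_sequence <- function(x, ...) {
  cat(sprintf("<burst_sequence> %s / %s / %s @ %g degC: %d bursts (%d spikes discarded)\n",
              x$preparation_id, x$neuron, x$epoch_id, x$temperature,
              nrow(x$bursts), x$n_discarded_spikes))
  invisible(x)
}

#' Detect bursts in every train of a collection
#'
#' @param trains A `spike_trains` collection.
#' @param params Optional named list mapping neuron labels to
#'   `list(gap_threshold =, min_spikes =)`; unlisted neurons fall back to
#'   [default_burst_params()].
#' @return A list of `burst_sequence` objects, one per train.
#' @export
detect_bursts_all <- function(trains, params = NULL) {
  lapply(trains, function(tr) {
    p <- params[[tr$neuron]]
    detect_bursts(tr, gap_threshold = p$gap_threshold,
                  min_spikes = p$min_spikes)
  })
}

#' Tidy table of bursts from one or more burst sequences
#'
#' @param seqs A `burst_sequence` or list of them.
#' @return A tibble with identity columns plus the per-burst metrics.
#' @export
bursts_tbl <- function(seqs) {
  if (inherits(seqs, "burst_sequence")) seqs <- list(seqs)
  dplyr::bind_rows(lapply(seqs, function(s) {
    dplyr::bind_cols(
      tibble::tibble(
        preparation_id = rep(s$preparation_id, nrow(s$bursts)),
        neuron = rep(s$neuron, nrow(s$bursts)),
        temperature = rep(s$temperature, nrow(s$bursts)),
        epoch_id = rep(s$epoch_id, nrow(s$bursts))
      ),
      s$bursts
    )
  }))
}

#' Per-temperature mean burst frequency
#'
#' Summarizes burst periods by temperature (pooling epochs and, if present,
#' preparations within each group as indicated by `by`). The mean burst
#' frequency is the mean over bursts of 1/period ("mean_rate"); the
#' alternative convention 1/mean(period) is also reported as
#' `frequency_inv_mean_period`. Bursts with undefined period (the last of
#' each epoch) are excluded. Groups with no defined period are flagged
#' `ok = FALSE` with missing values, and downstream Q10 computation skips
#' them.
#'
#' @param bursts A tidy burst table from [bursts_tbl()] (or a
#'   `burst_sequence` / list of them).
#' @param by Character vector of grouping columns, default
#'   `c("preparation_id", "neuron", "temperature")`.
#' @return A tibble with `n_periods`, `mean_period`, `sd_period`,
#'   `mean_frequency`, `frequency_inv_mean_period` and `ok` per group.
#' @export
burst_frequency_summary <- function(bursts,
                                    by = c("preparation_id", "neuron",
                                           "temperature")) {
  if (!is.data.frame(bursts)) bursts <- bursts_tbl(bursts)
  bursts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_periods = sum(!is.na(.data$period)),
      mean_period = mean(.data$period, na.rm = TRUE),
      sd_period = sd(.data$period, na.rm = TRUE),
      mean_frequency = mean(1 / .data$period, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ok = .data$n_periods >= 1,
      mean_period = ifelse(.data$ok, .data$mean_period, NA_real_),
      mean_frequency = ifelse(.data$ok, .data$mean_frequency, NA_real_),
      frequency_inv_mean_period = 1 / .data$mean_period
    )
}
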