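#' Spike train for one neuron in one epoch
#'
#' A `spike_train` holds the sorted spike times of a single neuron recorded
#' from one preparation during one epoch (a contiguous hold at one
#' temperature). Times are seconds relative to the epoch start and must be
#' strictly increasing, finite and non-negative.
#'
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing. May be empty.
#' @param neuron Neuron label, e.g. `"PD"` (fast pacemaker), `"LG"`
#'   (coupled slow unit) or `"DG"` (uncoupled slow unit). Arbitrary labels
#'   are allowed.
#' @param temperature Bath temperature in degrees Celsius for this epoch.
#' @param preparation_id Identifier of the preparation (animal).
#' @param epoch_id Identifier distinguishing repeated holds, default `"e0"`.
#'
#' @return An object of class `spike_train`.
#' @seealso [read_spike_table()], [detect_bursts()]
#' @export
#' @examples
#' spike_train(c(0.1, 0.2, 1.4), neuron = "PD", temperature = 11)
spike_train <- function(spike_times, neuron, temperature,
                        preparation_id = "prep1", epoch_id = "e0") {
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times) || (length(spike_times) && !all(is.finite(spike_times)))) {
    stop("spike_times must be finite and non-missing", call. = FALSE)
  }
  if (length(spike_times) && any(spike_times < 0)) {
    stop("spike_times must be non-negative", call. = FALSE)
  }
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike_times must be strictly increasing; see as_spike_train() ",
         "to sort and deduplicate raw times", call. = FALSE)
  }
  if (!is.finite(temperature)) stop("temperature must be finite", call. = FALSE)
  structure(
    list(
      preparation_id = as.character(preparation_id),
      neuron = as.character(neuron),
      temperature = as.numeric(temperature),
      epoch_id = as.character(epoch_id),
      spike_times = spike_times
    ),
    class = "spike_train"
  )
}

#' Coerce raw spike times to a spike train, sorting and deduplicating
#'
#' Unlike [spike_train()], tolerates unsorted input (sorted with a warning)
#' and duplicate timestamps (collapsed to a single spike with a warning);
#' duplicates are treated as sorting artifacts since two spikes of one
#' neuron cannot coincide.
#'
#' @inheritParams spike_train
#' @return A `spike_train`.
#' @export
as_spike_train <- function(spike_times, neuron, temperature,
                           preparation_id = "prep1", epoch_id = "e0") {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) {
    warning(sprintf("spike times for %s/%s/%s were out of order; sorted",
                    preparation_id, neuron, epoch_id), call. = FALSE)
    spike_times <- sort(spike_times)
  }
  dup <- duplicated(spike_times)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate spike time(s) for %s/%s/%s",
                    sum(dup), preparation_id, neuron, epoch_id), call. = FALSE)
    spike_times <- spike_times[!dup]
  }
  spike_train(spike_times, neuron = neuron, temperature = temperature,
              preparation_id = preparation_id, epoch_id = epoch_id)
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$spike_times)
  cat(sprintf("<spike_train> %s / %s / %s @ %g degC: %d spikes",
              x$preparation_id, x$neuron, x$epoch_id, x$temperature, n))
  if (n) cat(sprintf(" over %.2f s", diff(range(x$spike_times))))
  cat("\n")
  invisible(x)
}

#' Collection of spike trains
#'
#' A light wrapper around a list of [spike_train()] objects, as returned by
#' [read_spike_table()] and the synthetic generators.
#'
#' @param trains A list of `spike_train` objects.
#' @return An object of class `spike_trains` (a list).
#' @export
spike_trains <- function(trains) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  ok <- vapply(trains, inherits, logical(1), what = "spike_train")
  if (!all(ok)) stop("all elements must be spike_train objects", call. = FALSE)
  structure(trains, class = c("spike_trains", "list"))
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d train(s)\n", length(x)))
  for (tr in x) print(tr)
  invisible(x)
}

#' @export
`[.spike_trains` <- function(x, i) spike_trains(unclass(x)[i])

#' Tidy table of spikes from a collection of trains
#'
#' @param trains A `spike_trains` collection (or list of `spike_train`).
#' @return A tibble with columns `preparation_id`, `neuron`, `temperature_C`,
#'   `epoch_id`, `spike_time_s`, one row per spike.
#' @export
spikes_tbl <- function(trains) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (!length(trains)) {
    return(tibble::tibble(preparation_id = character(0),
                          neuron = character(0), temperature_C = numeric(0),
                          epoch_id = character(0), spike_time_s = numeric(0)))
  }
  rows <- lapply(trains, function(tr) {
    tibble::tibble(
      preparation_id = tr$preparation_id,
      neuron = tr$neuron,
      temperature_C = tr$temperature,
      epoch_id = tr$epoch_id,
      spike_time_s = tr$spike_times
    )
  })
  dplyr::bind_rows(rows)
}

#' Subset a collection of spike trains
#'
#' @param trains A `spike_trains` collection.
#' @param neuron,preparation_id,temperature Optional filters; `NULL` keeps all.
#' @return A `spike_trains` collection.
#' @export
filter_trains <- function(trains, neuron = NULL, preparation_id = NULL,
                          temperature = NULL) {
  keep <- vapply(trains, function(tr) {
    (is.null(neuron) || tr$neuron %in% neuron) &&
      (is.null(preparation_id) || tr$preparation_id %in% preparation_id) &&
      (is.null(temperature) || tr$temperature %in% temperature)
  }, logical(1))
  spike_trains(unclass(trains)[keep])
}
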