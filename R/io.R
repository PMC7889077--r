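required_spike_columns <- c("preparation_id", "neuron", "temperature_C",
                            "spike_time_s")

#' Read a delimited spike table
#'
#' Reads a plain-text spike table (one spike per row) into a collection of
#' [spike_train()] objects, one per (preparation, neuron, epoch). Required
#' header-named columns: `preparation_id`, `neuron`, `temperature_C`,
#' `spike_time_s`; `epoch_id` is optional and defaults to `"e0"`. Row order
#' does not matter. Out-of-order times are sorted and duplicate times within
#' one train are collapsed, each with a warning.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter, default comma.
#' @return A `spike_trains` collection, ordered by preparation, neuron,
#'   epoch and temperature.
#' @export
read_spike_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = delim,
                   colClasses = "character", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_spike_columns, names(df))
  if (length(missing_cols)) {
    stop("spike table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("epoch_id" %in% names(df))) df$epoch_id <- "e0"
  if (nrow(df) == 0) return(spike_trains(list()))

  times <- suppressWarnings(as.numeric(df$spike_time_s))
  if (anyNA(times)) {
    bad <- which(is.na(times))[1]
    stop(sprintf("non-numeric spike_time_s at data row %d: '%s'",
                 bad, df$spike_time_s[bad]), call. = FALSE)
  }
  temps <- suppressWarnings(as.numeric(df$temperature_C))
  if (anyNA(temps)) {
    bad <- which(is.na(temps))[1]
    stop(sprintf("non-numeric temperature_C at data row %d: '%s'",
                 bad, df$temperature_C[bad]), call. = FALSE)
  }
  df$spike_time_s <- times
  df$temperature_C <- temps

  key <- interaction(df$preparation_id, df$neuron, df$epoch_id,
                     df$temperature_C, drop = TRUE, lex.order = TRUE)
  groups <- split(df, key)
  trains <- lapply(groups, function(g) {
    as_spike_train(g$spike_time_s,
                   neuron = g$neuron[1],
                   temperature = g$temperature_C[1],
                   preparation_id = g$preparation_id[1],
                   epoch_id = g$epoch_id[1])
  })
  names(trains) <- NULL
  spike_trains(trains)
}

#' Write spike trains to a delimited table
#'
#' Inverse of [read_spike_table()]: `read_spike_table(write_spike_table(x))`
#' reproduces `x`. Times are written with 17 significant digits so the
#' round trip is exact in double precision.
#'
#' @param trains A `spike_trains` collection (or a single `spike_train`).
#' @param path Output file path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path, delim = ",") {
  tbl <- spikes_tbl(trains)
  if (nrow(tbl)) {
    tbl$spike_time_s <- sprintf("%.17g", tbl$spike_time_s)
    tbl$temperature_C <- sprintf("%.17g", tbl$temperature_C)
  }
  out <- tryCatch(
    write.table(tbl, file = path, sep = delim, row.names = FALSE,
                quote = FALSE),
    error = function(e) stop("cannot write spike table to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Temperature step protocol
#'
#' An ordered sequence of temperature holds, each a (temperature, duration)
#' pair; the synthetic generators emit one epoch per step.
#'
#' @param temperature Numeric vector of hold temperatures in degrees Celsius.
#' @param duration Hold durations in seconds (recycled if scalar); all > 0.
#' @return A tibble of class `temperature_protocol` with columns
#'   `temperature`, `duration` and `epoch_id`.
#' @export
#' @examples
#' temperature_protocol(seq(7, 23, by = 2), duration = 300)
temperature_protocol <- function(temperature, duration) {
  if (length(temperature) < 1) stop("at least one step required", call. = FALSE)
  duration <- rep_len(as.numeric(duration), length(temperature))
  if (any(!is.finite(temperature)) || any(!is.finite(duration)) ||
      any(duration <= 0)) {
    stop("temperatures must be finite and durations positive", call. = FALSE)
  }
  out <- tibble::tibble(
    temperature = as.numeric(temperature),
    duration = duration,
    epoch_id = sprintf("e%d", seq_along(temperature))
  )
  class(out) <- c("temperature_protocol", class(out))
  out
}
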