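#' Q10 temperature coefficient of a rate
#'
#' `q10 = (f_T / f_ref) ^ (10 / (T - T_ref))`: the factor by which the rate
#' changes per 10 degC. Vectorized over all arguments.
#'
#' @param f_t Rate (e.g. mean burst frequency, Hz) at temperature `temperature`.
#' @param f_ref Rate at the reference temperature.
#' @param temperature Temperature in degrees Celsius.
#' @param reference_temperature Reference temperature in degrees Celsius.
#' @return The dimensionless Q10.
#' @export
#' @examples
#' q10(2, 1, 21, 11)       # 2
#' q10(1.5, 1, 16, 11)     # 1.5^2 = 2.25
q10 <- function(f_t, f_ref, temperature, reference_temperature) {
  if (any(temperature == reference_temperature)) {
    stop("Q10 is undefined at the reference temperature (zero exponent)",
         call. = FALSE)
  }
  if (any(f_t <= 0, na.rm = TRUE) || any(f_ref <= 0, na.rm = TRUE)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  (f_t / f_ref)^(10 / (temperature - reference_temperature))
}

#' Per-preparation Q10 of burst frequency
#'
#' Computes, for each (preparation, neuron) — or for each neuron pooling
#' preparations — the mean burst frequency at every temperature, the Q10 at
#' every non-reference temperature, and a summary Q10. Two reductions are
#' available: `"mean"` (default) averages the per-temperature Q10s;
#' `"log_regression"` fits `log f ~ (T - T_ref)/10` by least squares and
#' returns `exp(slope)`, which weighs all temperatures jointly and is less
#' sensitive to noise amplification at temperatures close to the reference.
#'
#' @param bursts A tidy burst table from [bursts_tbl()] (or burst
#'   sequences). Must contain the reference temperature for every group.
#' @param reference_temperature Reference temperature, default 11 degC.
#' @param method `"mean"` or `"log_regression"` (see above).
#' @param frequency `"mean_rate"` (mean of 1/period, default) or
#'   `"inverse_mean_period"`.
#' @param pool_preparations If `TRUE`, bursts are pooled across preparations
#'   before computing per-temperature frequencies, yielding one
#'   population-level Q10 per neuron.
#' @return An object of class `thermal_scaling_result`: a list with
#'   `per_temperature` (tibble of frequencies and per-temperature Q10s) and
#'   `summary` (one row per group with the summary Q10).
#' @export
preparation_q10 <- function(bursts, reference_temperature = 11,
                            method = c("mean", "log_regression"),
                            frequency = c("mean_rate", "inverse_mean_period"),
                            pool_preparations = FALSE) {
  method <- match.arg(method)
  frequency <- match.arg(frequency)
  by <- if (pool_preparations) c("neuron", "temperature") else
    c("preparation_id", "neuron", "temperature")
  freq <- burst_frequency_summary(bursts, by = by)
  freq$frequency <- if (frequency == "mean_rate") freq$mean_frequency else
    freq$frequency_inv_mean_period
  group_cols <- setdiff(by, "temperature")

  per_temp <- freq |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(g, key) {
      ref <- g$frequency[g$temperature == reference_temperature & g$ok]
      if (length(ref) != 1) {
        stop("no usable reference-temperature (", reference_temperature,
             " degC) frequency for group: ",
             paste(unlist(key), collapse = "/"), call. = FALSE)
      }
      g <- g[g$temperature != reference_temperature & g$ok, , drop = FALSE]
      g$q10 <- q10(g$frequency, ref, g$temperature, reference_temperature)
      g$f_ref <- ref
      g
    }) |>
    dplyr::ungroup()

  summarise_one <- function(g) {
    if (method == "mean") return(mean(g$q10))
    x <- (g$temperature - reference_temperature) / 10
    y <- log(g$frequency / g$f_ref[1])
    # regression through the origin: at T_ref, log(f/f_ref) = 0 by definition
    exp(sum(x * y) / sum(x^2))
  }
  summary <- per_temp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(g, key) {
      tibble::tibble(reference_temperature = reference_temperature,
                     n_temperatures = nrow(g),
                     q10 = summarise_one(g))
    }) |>
    dplyr::ungroup()

  structure(list(per_temperature = per_temp, summary = summary,
                 method = method, frequency = frequency),
            class = "thermal_scaling_result")
}

#' @export
print.thermal_scaling_result <- function(x, ...) {
  cat(sprintf("<thermal_scaling_result> method = %s, frequency = %s\n",
              x$method, x$frequency))
  print(x$summary)
  invisible(x)
}

#' Compare Q10s between two groups (e.g. the fast and the slow rhythm)
#'
#' A t test on per-preparation Q10s, paired by preparation by default so
#' each animal contributes equally. The degenerate case of zero-variance,
#' nonzero-mean paired differences (t infinite) is flagged rather than
#' raised as an error; identical groups give t = 0, p = 1.
#'
#' @param group_a,group_b Numeric vectors of per-preparation Q10s. For a
#'   paired test they must be equal length, matched by preparation.
#' @param paired Logical, default `TRUE`.
#' @return A list with `t`, `p`, `df`, `n`, `mean_difference` (paired only)
#'   and `degenerate`.
#' @export
compare_q10 <- function(group_a, group_b, paired = TRUE) {
  n <- length(group_a)
  if (paired && length(group_b) != n) {
    stop("paired comparison requires equal-length, matched groups",
         call. = FALSE)
  }
  if (n < 2 || length(group_b) < 2) stop("need at least 2 values per group",
                                         call. = FALSE)
  if (paired) {
    d <- group_a - group_b
    if (sd(d) == 0) {
      if (mean(d) == 0) {
        return(list(t = 0, p = 1, df = n - 1L, n = n, mean_difference = 0,
                    degenerate = TRUE))
      }
      return(list(t = sign(mean(d)) * Inf, p = NA_real_, df = n - 1L, n = n,
                  mean_difference = mean(d), degenerate = TRUE))
    }
  }
  tt <- t.test(group_a, group_b, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = n,
       mean_difference = if (paired) mean(group_a - group_b) else NA_real_,
       degenerate = FALSE)
}
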