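#' Configuration for a full analysis run
#'
#' Exactly one of `input_path` (a spike table on disk) or `generator` (a
#' [generator_config()], simulated over `protocol`) must be given. A seed
#' is mandatory: there is no silent nondeterminism. Per-stage seeds are
#' derived from it by fixed offsets so stages can be rerun independently
#' yet reproducibly.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for the whole run.
#' @param input_path Optional path to a spike table (see
#'   [read_spike_table()]).
#' @param generator Optional [generator_config()].
#' @param protocol A [temperature_protocol()]; required with `generator`.
#'   Defaults to 2 degC steps from 7 to 23 degC, 300 s each.
#' @param pacemaker_neuron Label of the fast unit, default `"PD"`.
#' @param burst_params Optional per-neuron overrides, as in
#'   [detect_bursts_all()].
#' @param reference_temperature Q10 reference, default 11 degC.
#' @param n_boot,n_shuffle Resampling counts, default 1000 each.
#' @param alpha Family-wise significance level, default 0.05.
#' @param first_n Burst starts per unit for phase analysis, default 40.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed, input_path = NULL, generator = NULL,
                       protocol = temperature_protocol(seq(7, 23, by = 2), 300),
                       pacemaker_neuron = "PD", burst_params = NULL,
                       reference_temperature = 11, n_boot = 1000,
                       n_shuffle = 1000, alpha = 0.05, first_n = 40) {
  if (is.null(input_path) == is.null(generator)) {
    stop("exactly one of input_path or generator must be supplied",
         call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), input_path = input_path,
         generator = generator, protocol = protocol,
         pacemaker_neuron = pacemaker_neuron, burst_params = burst_params,
         reference_temperature = reference_temperature, n_boot = n_boot,
         n_shuffle = n_shuffle, alpha = alpha, first_n = first_n),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `generator` and `protocol`
#' are nested maps (`protocol: {temperature: [...], duration: [...]}`).
#'
#' @param path Path to a YAML config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) y$generator <- do.call(generator_config, y$generator)
  if (!is.null(y$protocol)) y$protocol <- do.call(temperature_protocol, y$protocol)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> detect bursts -> Q10 -> integer coupling -> phase
#' locking, writing each stage's output under `config$out_dir` and a
#' `manifest.json` with the md5 hash of every file, so identical config and
#' seed yield identical manifests. Every exclusion (discarded spikes,
#' dropped pairs, excluded phase units) is counted in the manifest log.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate / load -------------------------------------------------
  trains <- stage("simulate", {
    if (!is.null(config$generator)) {
      tr <- generate_recording(config$generator, config$protocol,
                               preparation_id = "sim1",
                               seed = config$seed + 1000L)
      spike_path <- file.path(config$out_dir, "spikes.csv")
      write_spike_table(tr, spike_path)
      truth_path <- file.path(config$out_dir, "ground_truth.json")
      jsonlite::write_json(attr(tr, "coupled_truth"), truth_path, digits = NA)
      paths <- c(paths, spike_path, truth_path)
      tr
    } else {
      read_spike_table(config$input_path)
    }
  })

  # -- bursts ----------------------------------------------------------
  seqs <- stage("bursts", detect_bursts_all(trains, config$burst_params))
  btbl <- bursts_tbl(seqs)
  log$n_discarded_spikes <- sum(vapply(seqs, `[[`, integer(1),
                                       "n_discarded_spikes"))
  p <- file.path(config$out_dir, "bursts.csv")
  write.table(as.data.frame(btbl), p, sep = ",", row.names = FALSE,
              quote = FALSE)
  paths <- c(paths, p)

  pacemaker <- config$pacemaker_neuron
  is_fast <- vapply(seqs, function(s) s$neuron == pacemaker, logical(1))
  slow_neurons <- unique(vapply(seqs[!is_fast], `[[`, character(1), "neuron"))

  # -- q10 -------------------------------------------------------------
  q10_res <- stage("q10", preparation_q10(
    btbl, reference_temperature = config$reference_temperature))
  p <- file.path(config$out_dir, "q10.csv")
  write.table(as.data.frame(q10_res$summary), p, sep = ",",
              row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  # -- coupling --------------------------------------------------------
  coupling <- stage("coupling", {
    out <- list()
    for (nm in slow_neurons) {
      slow_seqs <- seqs[vapply(seqs, function(s) s$neuron == nm, logical(1))]
      prs <- withCallingHandlers(
        pair_periods_all(slow_seqs, seqs[is_fast]),
        message = function(m) invokeRestart("muffleMessage"))
      if (nrow(prs) < 3) next
      an <- integer_coupling_analysis(prs, n_boot = config$n_boot,
                                      n_shuffle = config$n_shuffle,
                                      alpha = config$alpha,
                                      seed = config$seed + 2000L)
      out[[nm]] <- list(
        pairs = prs,
        per_temperature = lapply(unname(an), function(r) {
          r[c("temperature", "n", "area", "D", "p", "threshold",
              "significant")]
        }),
        ratio_trend = attr(an, "ratio_trend")
      )
    }
    out
  })
  p <- file.path(config$out_dir, "coupling.json")
  jsonlite::write_json(
    lapply(coupling, function(x) x[c("per_temperature", "ratio_trend")]),
    p, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, p)
  pairs_all <- dplyr::bind_rows(lapply(names(coupling), function(nm) {
    dplyr::mutate(coupling[[nm]]$pairs, neuron = nm)
  }))
  p <- file.path(config$out_dir, "period_pairs.csv")
  write.table(as.data.frame(pairs_all), p, sep = ",", row.names = FALSE,
              quote = FALSE)
  paths <- c(paths, p)

  # -- phase -----------------------------------------------------------
  n_excluded_units <- 0L
  phase <- stage("phase", {
    out <- list()
    for (nm in slow_neurons) {
      slow_seqs <- seqs[vapply(seqs, function(s) s$neuron == nm, logical(1))]
      temps <- sort(unique(vapply(slow_seqs, `[[`, numeric(1), "temperature")))
      for (temp in temps) {
        ss <- slow_seqs[vapply(slow_seqs, function(s) s$temperature == temp,
                               logical(1))]
        ff <- seqs[is_fast][vapply(seqs[is_fast],
                                   function(s) s$temperature == temp,
                                   logical(1))]
        if (!length(ff)) next
        samp <- withCallingHandlers(
          burst_start_phases(ss, ff, first_n = config$first_n),
          message = function(m) invokeRestart("muffleMessage"))
        if (is.null(samp)) { n_excluded_units <- n_excluded_units + 1L; next }
        st <- phase_stats(samp)
        out[[length(out) + 1L]] <- list(
          neuron = nm, fast_neuron = pacemaker, temperature = temp,
          n = st$n, mean_phase = st$mean_phase, R = st$R,
          circ_sd = st$circ_sd, rayleigh_z = st$z, rayleigh_p = st$p)
      }
    }
    out
  })
  log$n_excluded_phase_units <- n_excluded_units
  p <- file.path(config$out_dir, "phase.json")
  jsonlite::write_json(phase, p, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, p)

  # -- manifest --------------------------------------------------------
  paths <- unique(paths)
  manifest <- list(
    seed = config$seed,
    reference_temperature = config$reference_temperature,
    files = lapply(setNames(paths, basename(paths)),
                   function(p) unname(md5sum(p))),
    log = log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
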