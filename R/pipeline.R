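#' Detected thresholds for a simulated cohort
#'
#' Simulates a population and runs the amplitude extraction and threshold
#' detection on every cell.
#'
#' @param pop A [population_spec()].
#' @param protocol A `voltage_protocol`.
#' @param multiplier Noise-criterion multiplier.
#' @param steady_window Steady window for the threshold statistic, ms
#'   (default 275--300).
#' @return Data.frame: `cell_id`, `v_threshold` (NA when none detected),
#'   `left_censored`.
#' @export
population_thresholds <- function(pop, protocol, multiplier = 2,
                                  steady_window = c(275, 300)) {
  recs <- simulate_population(pop, protocol)
  res <- lapply(recs, function(r) {
    iv <- extract_amplitudes(r, steady_window = steady_window)
    detect_threshold(iv, multiplier = multiplier)
  })
  data.frame(cell_id = seq_along(recs),
             v_threshold = vapply(res, function(x) x$v_threshold, numeric(1)),
             left_censored = vapply(res, function(x) x$left_censored,
                                    logical(1)))
}

#' Configuration for a named end-to-end experiment
#'
#' @param name One of `"ca_dependence"` (concentration series + Hill fit of
#'   mean thresholds), `"gain_of_function"` (WT vs T498I at zero and 3 uM
#'   Ca2+ with Mann-Whitney comparisons), `"construct_comparison"`
#'   (HEK/CHO/913 threshold table at 3 uM), `"scrambling"` (annexin-V
#'   cohort with onset latencies).
#' @param base_seed Base RNG seed for all stages.
#' @param output_dir Optional directory; when given, the resolved config,
#'   per-cell CSV and summary JSON are written there.
#' @param multiplier Noise-criterion multiplier.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(name = c("ca_dependence", "gain_of_function",
                                       "construct_comparison", "scrambling"),
                              base_seed = 1, output_dir = NULL,
                              multiplier = 2) {
  name <- match.arg(name)
  structure(list(name = name, base_seed = as.integer(base_seed),
                 output_dir = output_dir, multiplier = multiplier),
            class = "experiment_config")
}

# group run: one parameter set, one ca, one n -> summary row + cells
.run_group <- function(set, ca, n, base_seed, protocol, multiplier,
                       label = NULL) {
  g <- default_params(set)
  pop <- population_spec(g, ca, n, base_seed)
  th <- population_thresholds(pop, protocol, multiplier = multiplier)
  th$set <- set; th$ca_uM <- ca
  lab <- if (is.null(label)) paste0(set, " @ ", ca, " uM") else label
  sm <- summarize_group(th$v_threshold, lab)
  sm$set <- set; sm$ca_uM <- ca
  sm$n_simulated <- n
  list(cells = th, summary = sm)
}

#' Run a named experiment end to end
#'
#' Simulate -> analyze -> summarize, deterministically from
#' `config$base_seed`. The concentration-series experiment uses the
#' per-group cell counts of the original study (7, 5, 10, 7, 7, 7 cells at
#' 0, 1, 3, 9, 100, 240 uM Ca2+) and fits the modified Hill equation to the
#' group mean thresholds weighted by 1/SEM^2; the gain-of-function
#' experiment compares WT and T498I cohorts at matched Ca2+ with the
#' Mann-Whitney U test.
#'
#' @param config An [experiment_config()].
#' @return List with elements depending on the experiment: `cells`
#'   (per-cell data.frame), `summary` (group summaries), plus `hill`
#'   (`hill_fit`) for `ca_dependence`, `comparisons` (data.frame with
#'   Mann-Whitney p-values) for `gain_of_function`, `onsets` for
#'   `scrambling`. When `config$output_dir` is set, writes `cells.csv`,
#'   `summary.json` and `config.json` there.
#' @export
#' @examples
#' \donttest{
#' res <- run_experiment(experiment_config("scrambling", base_seed = 1))
#' res$summary
#' }
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$base_seed
  mult <- config$multiplier
  proto180 <- build_step_protocol()                      # -100..+180
  proto140 <- build_step_protocol(stop_mV = 140)         # -100..+140
  out <- switch(config$name,
    ca_dependence = {
      series <- data.frame(ca = c(0, 1, 3, 9, 100, 240),
                           n = c(7, 5, 10, 7, 7, 7))
      runs <- lapply(seq_len(nrow(series)), function(i)
        .run_group("WT-CHO", series$ca[i], series$n[i],
                   seed + i * 1000L, proto180, mult))
      cells <- do.call(rbind, lapply(runs, `[[`, "cells"))
      summ <- do.call(rbind, lapply(runs, `[[`, "summary"))
      w <- ifelse(summ$sem > 0, 1 / summ$sem^2, NA)
      w[!is.finite(w)] <- max(w[is.finite(w)], 1)
      hill <- fit_hill(summ$ca_uM, summ$mean, weights = w)
      list(cells = cells, summary = summ, hill = hill)
    },
    gain_of_function = {
      plan <- data.frame(set = c("WT-HEK", "WT-HEK", "T498I", "T498I"),
                         ca = c(0, 3, 0, 3), n = c(19, 31, 11, 12))
      runs <- lapply(seq_len(nrow(plan)), function(i)
        .run_group(plan$set[i], plan$ca[i], plan$n[i], seed + i * 1000L,
                   proto140, mult))
      cells <- do.call(rbind, lapply(runs, `[[`, "cells"))
      summ <- do.call(rbind, lapply(runs, `[[`, "summary"))
      cmp <- do.call(rbind, lapply(c(0, 3), function(cc) {
        aa <- cells$v_threshold[cells$set == "WT-HEK" & cells$ca_uM == cc]
        bb <- cells$v_threshold[cells$set == "T498I" & cells$ca_uM == cc]
        mw <- compare_groups(aa[is.finite(aa)], bb[is.finite(bb)])
        data.frame(ca_uM = cc, test = "mann-whitney", p = mw$p,
                   exact = mw$exact)
      }))
      list(cells = cells, summary = summ, comparisons = cmp)
    },
    construct_comparison = {
      plan <- data.frame(set = c("WT-HEK", "WT-CHO-3uM", "WT-913"),
                         ca = c(3, 3, 3), n = c(31, 8, 18))
      runs <- lapply(seq_len(nrow(plan)), function(i)
        .run_group(plan$set[i], plan$ca[i], plan$n[i], seed + i * 1000L,
                   proto180, mult))
      list(cells = do.call(rbind, lapply(runs, `[[`, "cells")),
           summary = do.call(rbind, lapply(runs, `[[`, "summary")))
    },
    scrambling = {
      coh <- simulate_scrambling_cohort(scrambling_params(),
                                        n_transfected = 10, n_control = 4,
                                        base_seed = seed)
      det <- coh$onsets$latency_detected[coh$onsets$transfected]
      summ <- summarize_group(det[is.finite(det)], "onset latency (min)")
      summ$n_controls_detected <-
        sum(is.finite(coh$onsets$latency_detected[!coh$onsets$transfected]))
      list(cells = coh$onsets, summary = summ, traces = coh$traces)
    })
  out$config <- config
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$cells, file.path(config$output_dir, "cells.csv"),
                     row.names = FALSE)
    summ_list <- list(summary = out$summary)
    if (!is.null(out$hill))
      summ_list$hill <- out$hill[c("base", "max", "ec50", "h", "converged")]
    if (!is.null(out$comparisons)) summ_list$comparisons <- out$comparisons
    jsonlite::write_json(summ_list,
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    jsonlite::write_json(c(unclass(config),
                           list(package_version =
                                  as.character(utils::packageVersion("anophys")))),
                         file.path(config$output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Recalibrate the bundled parameter sets
#'
#' Re-runs the detection-offset calibration ([calibrate_detection_offset()])
#' and the anion-permeability calibration for every anchor stored in the
#' parameter-set file, and writes an updated file. The bundled file at
#' `inst/extdata/parameter_sets.json` ships pre-calibrated; this function
#' regenerates it (it is what `scripts/calibrate_defaults.R` runs).
#'
#' @param path Parameter-set JSON to read (default: bundled file).
#' @param out_path File to write (default: overwrite `path`).
#' @param n_mc Monte-Carlo cells per calibration evaluation.
#' @param seed RNG seed for calibration.
#' @return Invisibly, the updated configuration list.
#' @export
calibrate_defaults <- function(path = NULL, out_path = path, n_mc = 200,
                               seed = 20260101) {
  if (is.null(path))
    path <- system.file("extdata", "parameter_sets.json", package = "anophys")
  if (is.null(out_path)) out_path <- path
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  perm <- permeation_spec()
  for (nm in names(cfg$parameter_sets)) {
    s <- cfg$parameter_sets[[nm]]
    if (is.null(s$anchors) || !length(s$anchors)) next
    anchors <- as.data.frame(s$anchors)
    g <- default_params(nm, path = path)
    g$delta <- 0
    deltas <- vapply(seq_len(nrow(anchors)), function(i) {
      proto <- build_step_protocol(stop_mV = anchors$protocol_stop_mV[i])
      calibrate_detection_offset(g, perm, proto, anchors$ca[i],
                                 anchors$target_mV[i], n_mc = n_mc,
                                 seed = seed)
    }, numeric(1))
    cfg$parameter_sets[[nm]]$delta_table <-
      data.frame(ca = anchors$ca, delta = deltas)
  }
  jsonlite::write_json(cfg, out_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(cfg)
}
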