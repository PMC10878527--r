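# Pipeline entry points: protocol runs, fitting, report assembly -------------

# Short stable polynomial hash (hex) of a resolved configuration, stamped
# into every output file so results can be traced to the exact settings.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

run_stamp <- function(config) {
  list(
    package = "vegfrtraffic",
    version = as.character(utils::packageVersion("vegfrtraffic")),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Run a named perturbation protocol and write tidy outputs
#'
#' Simulates a protocol preset from the steady state of the given parameters
#' and writes the tidy trajectory table (CSV) plus the resolved
#' configuration (JSON) to an output directory.
#'
#' @param preset `"none"`, `"chx"`, `"chq"`, `"sirna_rab4"`,
#'   `"sirna_rab11"` or `"sirna_double"`.
#' @param params Parameter set (default: the calibrated HUVEC consensus).
#' @param hours Protocol duration in hours.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param by_hours Output grid spacing, hours.
#' @return Invisibly, a list with `trajectory`, `table` and `config`.
#' @export
run_protocol <- function(preset = c("none", "chx", "chq", "sirna_rab4",
                                    "sirna_rab11", "sirna_double"),
                         params = huvec_params(), hours = 24,
                         out_dir = NULL, by_hours = 0.5) {
  preset <- match.arg(preset)
  pert <- switch(preset,
    none = perturbation("NONE"),
    chx = perturbation("CHX"),
    chq = perturbation("CHQ"),
    sirna_rab4 = perturbation("SIRNA_RAB4"),
    sirna_rab11 = perturbation("SIRNA_RAB11"),
    sirna_double = perturbation("SIRNA_DOUBLE")
  )
  config <- list(preset = preset, hours = hours, by_hours = by_hours,
                 params = unclass(params))
  ss <- steady_state(params)
  traj <- simulate_protocol(params, ss,
                            times = seq(0, hours * 3600, by = by_hours * 3600),
                            perturbation_spec = pert)
  tab <- trajectory_to_table(traj)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, paste0("protocol_", preset, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(c(run_stamp(config), config),
                         file.path(out_dir, paste0("protocol_", preset, "_config.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(trajectory = traj, table = tab, config = config))
}

#' Run the multistart calibration and write ensemble outputs
#'
#' Fits the trafficking parameters to a dataset (the in-lab HUVEC dataset by
#' default, or a CSV supplied via `dataset_file`), then writes the ensemble
#' as JSON lines (one fit per line), the consensus parameter configuration
#' (YAML), and the identifiability table (CSV).
#'
#' @param dataset A `calibration_dataset`; defaults to [huvec_dataset()].
#' @param dataset_file Optional CSV path overriding `dataset`.
#' @param n_starts,seed Multistart settings (see [multistart_fit()]).
#' @param out_dir Output directory; `NULL` skips writing.
#' @return Invisibly, a list with `ensemble`, `consensus` (from
#'   [summarize_fits()]) and `identifiability`.
#' @export
run_fit <- function(dataset = huvec_dataset(), dataset_file = NULL,
                    n_starts = 100, seed = 1, out_dir = NULL) {
  if (!is.null(dataset_file)) {
    if (!file.exists(dataset_file)) {
      stop("dataset file not found: ", dataset_file)
    }
    dataset <- read_dataset_csv(dataset_file)
  }
  config <- list(n_starts = n_starts, seed = seed,
                 dataset = as.data.frame(dataset))
  ens <- multistart_fit(dataset, n_starts = n_starts, seed = seed)
  consensus <- summarize_fits(ens)
  ident <- if (consensus$n_converged >= 3) initial_final_correlation(ens) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- run_stamp(config)
    lines <- vapply(ens$fits, function(f) {
      jsonlite::toJSON(list(
        initial = f$initial, trafficking = as.vector(f$trafficking),
        k_prod = f$k_prod, cost = f$cost, converged = f$converged,
        info = f$info
      ), auto_unbox = TRUE, digits = NA)
    }, "")
    writeLines(lines, file.path(out_dir, "ensemble.jsonl"))
    write_params_yaml(consensus$params, file.path(out_dir, "consensus_params.yaml"))
    utils::write.csv(consensus$summary, file.path(out_dir, "parameter_summary.csv"),
                     row.names = FALSE)
    if (!is.null(ident)) {
      utils::write.csv(ident, file.path(out_dir, "identifiability.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(c(stamp, config[c("n_starts", "seed")]),
                         file.path(out_dir, "fit_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(ensemble = ens, consensus = consensus,
                 identifiability = ident, config = config))
}

#' Assemble the headline report for a parameter set
#'
#' Collects the quantities the analysis is about -- steady-state surface and
#' internal receptor levels, surface percentages, surface-residence and
#' whole-cell CHX half-lives, recycling:degradation ratios, and the full
#' transport-rate (flux) table -- into one machine-readable structure, and
#' optionally writes it as JSON plus a human-readable text summary.
#'
#' @param params Parameter set to report on (default: calibrated HUVEC
#'   consensus).
#' @param dataset Dataset for the matched-prediction block (default:
#'   [huvec_dataset()]).
#' @param out_dir Output directory; `NULL` skips writing.
#' @return Invisibly, the report list.
#' @export
run_report <- function(params = huvec_params(), dataset = huvec_dataset(),
                       out_dir = NULL) {
  config <- list(params = unclass(params))
  network <- expand_reactions(params)
  ss <- steady_state(params, network = network)
  agg <- aggregate_state(ss)
  fluxes <- compute_fluxes(params, ss)

  chx <- simulate_protocol(params, ss, times = seq(0, 24 * 3600, by = 60),
                           perturbation_spec = perturbation("CHX"),
                           network = network)
  half_lives_min <- vapply(RECEPTORS, function(r)
    whole_cell_half_life(chx, r) / 60, 0)
  surf_res_min <- vapply(RECEPTORS, function(r)
    surface_residence_half_life(params$trafficking["k_int", r]) / 60, 0)
  ratios <- vapply(RECEPTORS, function(r)
    recycling_degradation_ratio(params, r), 0)

  matched <- predict_dataset(params, dataset, network = network)
  report <- list(
    stamp = run_stamp(config),
    steady_state = agg,
    surface_residence_half_life_min = surf_res_min,
    whole_cell_chx_half_life_min = half_lives_min,
    recycling_degradation_ratio = ratios,
    fluxes = as.data.frame(fluxes),
    net_fluxes = attr(fluxes, "net"),
    matched_predictions = data.frame(
      dataset[, c("receptor", "type", "time_h")],
      observed = dataset$value,
      predicted = matched$predicted
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    txt <- c(
      sprintf("vegfrtraffic report (version %s, config %s)",
              report$stamp$version, report$stamp$config_hash),
      "",
      "Steady state (receptors/cell):",
      utils::capture.output(print(agg, digits = 4)),
      "",
      sprintf("Surface residence half-life (min): R1 %.1f, R2 %.1f, N1 %.1f",
              surf_res_min[1], surf_res_min[2], surf_res_min[3]),
      sprintf("Whole-cell CHX half-life (min):    R1 %.1f, R2 %.1f, N1 %s",
              half_lives_min[1], half_lives_min[2],
              ifelse(is.na(half_lives_min[3]), "stable", sprintf("%.1f", half_lives_min[3]))),
      sprintf("Recycling:degradation ratio:       R1 %.2f, R2 %.2f, N1 %.0f",
              ratios[1], ratios[2], ratios[3])
    )
    writeLines(txt, file.path(out_dir, "report.txt"))
  }
  invisible(report)
}
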