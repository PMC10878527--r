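# Local and global sensitivity analysis ---------------------------------------

SENSITIVITY_PARAMS <- function() {
  c(as.vector(outer(TRAFFIC_PROCESSES, RECEPTORS, paste, sep = ".")),
    paste0("k_prod.", RECEPTORS))
}

SENSITIVITY_OUTPUTS <- function() {
  as.vector(outer(c("total", "surface", "internal", "pct_surface"),
                  RECEPTORS, paste, sep = "."))
}

steady_outputs <- function(params, network = NULL) {
  ss <- steady_state(params, network = network)
  pools <- receptor_pools(ss)
  surface <- pools[, "SURFACE"]
  internal <- pools[, "RAB4"] + pools[, "RAB11"]
  total <- surface + internal
  out <- rbind(total = total, surface = surface, internal = internal,
               pct_surface = 100 * surface / total)
  stats::setNames(as.vector(out),
                  as.vector(outer(rownames(out), colnames(out), paste, sep = ".")))
}

#' Local (one-at-a-time) relative sensitivity analysis
#'
#' Each of the 18 parameters (15 trafficking plus 3 production rates) is
#' increased by the fraction `delta` (default 5%) one at a time; the model is
#' brought to its new steady state and the relative sensitivity of each
#' output is reported as (% change in output) / (% change in parameter).
#' Outputs are per-receptor whole-cell, surface, and internal levels and the
#' surface percentage. Production rates are treated as free parameters here
#' (not re-solved), since the question is how the cell's outputs respond to
#' changes in its production machinery.
#'
#' @param params Baseline parameter set, e.g. [huvec_params()].
#' @param delta Fractional forward perturbation (0.05 = +5%).
#' @return A `sensitivity_matrix`: numeric matrix, rows = parameters,
#'   columns = outputs; entries are dimensionless relative sensitivities
#'   (`NA` where the perturbed steady state was infeasible, with a warning).
#' @export
local_sensitivity <- function(params, delta = 0.05) {
  stopifnot(delta > 0)
  network <- expand_reactions(params)
  base <- steady_outputs(params, network)
  if (any(base[grep("^total", names(base))] <= 0)) {
    stop("baseline outputs must be positive for relative sensitivities")
  }
  par_names <- SENSITIVITY_PARAMS()
  out <- matrix(NA_real_, nrow = length(par_names), ncol = length(base),
                dimnames = list(par_names, names(base)))
  for (pn in par_names) {
    pp <- apply_param_factors(params, stats::setNames(list(1 + delta), pn))
    pert <- tryCatch(steady_outputs(pp, network), error = function(e) NULL)
    if (is.null(pert)) {
      warning("infeasible perturbed steady state for ", pn, "; entries flagged NA")
      next
    }
    out[pn, ] <- (pert / base - 1) / delta
  }
  class(out) <- c("sensitivity_matrix", class(out))
  out
}

#' Export a sensitivity matrix as a tidy table
#'
#' @param x A `sensitivity_matrix` from [local_sensitivity()].
#' @param path Optional CSV path.
#' @return data.frame with columns `parameter`, `output`, `value`.
#' @export
sensitivity_to_table <- function(x, path = NULL) {
  out <- data.frame(
    parameter = rep(rownames(x), times = ncol(x)),
    output = rep(colnames(x), each = nrow(x)),
    value = as.vector(x)
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Global one-at-a-time parameter scan
#'
#' Varies each of the 18 parameters over a log-spaced multiplier grid
#' spanning four orders of magnitude around the supplied optimum (1/100x to
#' 100x by default), and records, at every grid point, the calibration cost
#' and the full set of dataset-matched predictions (which rerun the CHX and
#' siRNA protocols, not just the steady state). Production rates are varied
#' directly; when a trafficking parameter is varied, production rates are
#' re-solved by the inner loop exactly as during calibration.
#'
#' @param params Consensus/optimum parameter set.
#' @param dataset Calibration dataset defining the predictions and cost.
#' @param grid_points Number of multipliers per parameter (odd values
#'   include the baseline multiplier 1).
#' @param range Two-sided multiplier range (default `c(1e-2, 1e2)`).
#' @return A `global_scan`: data.frame with columns `parameter`,
#'   `multiplier`, `cost`, `ok`, and one `pred_<i>` column per dataset row.
#' @export
global_scan <- function(params, dataset, grid_points = 9,
                        range = c(1e-2, 1e2)) {
  stopifnot(grid_points >= 3)
  mult <- 10^seq(log10(range[1]), log10(range[2]), length.out = grid_points)
  # the grid must contain the baseline for the scan to be anchored
  if (!any(abs(mult - 1) < 1e-12)) mult <- sort(c(mult, 1))
  par_names <- SENSITIVITY_PARAMS()
  network <- expand_reactions(params)

  scan_cost <- function(predicted) {
    # same weighting and detection floor as traffic_cost()
    res <- sqrt(dataset$weight) * (predicted - dataset$value) /
      pmax(abs(dataset$value), 0.01)
    sum(res^2)
  }
  eval_point <- function(pp) {
    pred <- tryCatch(predict_dataset(pp, dataset, network = network),
                     error = function(e) NULL)
    if (is.null(pred)) {
      list(cost = NA_real_, pred = rep(NA_real_, nrow(dataset)), ok = FALSE)
    } else {
      list(cost = scan_cost(pred$predicted), pred = pred$predicted, ok = TRUE)
    }
  }

  rows <- list()
  for (pn in par_names) {
    for (m in mult) {
      pp <- apply_param_factors(params, stats::setNames(list(m), pn))
      if (startsWith(pn, "k_prod")) {
        # production is a directly varied parameter: evaluate predictions
        # without the inner re-solve, holding the edited rate fixed
        ev <- tryCatch({
          net2 <- update_network_rates(network, pp)
          ss <- steady_state(pp, network = net2)
          pr <- predict_dataset_fixed_production(pp, dataset, net2, ss)
          list(cost = scan_cost(pr), pred = pr, ok = TRUE)
        }, error = function(e) list(cost = NA_real_,
                                    pred = rep(NA_real_, nrow(dataset)),
                                    ok = FALSE))
      } else {
        ev <- eval_point(pp)
      }
      rows[[length(rows) + 1L]] <- c(
        list(parameter = pn, multiplier = m, cost = ev$cost, ok = ev$ok),
        stats::setNames(as.list(ev$pred), paste0("pred_", seq_along(ev$pred)))
      )
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  class(out) <- c("global_scan", "data.frame")
  out
}

# Predictions for a dataset with production rates held fixed (no inner
# solve); used when scanning the production rates themselves.
predict_dataset_fixed_production <- function(params, dataset, network, ss) {
  pools <- receptor_pools(ss)
  surface <- pools[, "SURFACE"]
  internal <- pools[, "RAB4"] + pools[, "RAB11"]
  pct <- 100 * surface / (surface + internal)

  chx_hours <- sort(unique(dataset$time_h[dataset$type == "chx_foldchange"]))
  chx_fc <- NULL
  if (length(chx_hours) > 0) {
    traj <- simulate_protocol(params, ss, times = c(0, chx_hours * 3600),
                              perturbation_spec = perturbation("CHX"),
                              network = network)
    chx_fc <- normalize_to_control(trajectory_totals(traj))
    rownames(chx_fc) <- as.character(traj$time / 3600)
  }
  sir_hours <- unique(dataset$time_h[dataset$type == "sirna_double_foldchange"])
  sir_fc <- NULL
  if (length(sir_hours) > 0) {
    traj <- simulate_protocol(params, ss, times = c(0, sort(sir_hours) * 3600),
                              perturbation_spec = perturbation("SIRNA_DOUBLE"),
                              network = network)
    sir_fc <- normalize_to_control(trajectory_totals(traj))
    rownames(sir_fc) <- as.character(traj$time / 3600)
  }
  vapply(seq_len(nrow(dataset)), function(i) {
    r <- dataset$receptor[i]
    switch(dataset$type[i],
      surface_count = surface[[r]],
      surface_percent = pct[[r]],
      sirna_double_foldchange = sir_fc[as.character(dataset$time_h[i]), r],
      chx_foldchange = chx_fc[as.character(dataset$time_h[i]), r]
    )
  }, 0)
}
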