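# Calibration: dataset, inner production solve, cost, multistart LM fit ------

# Default protocol settings shared by the cost function, the synthetic-data
# generator and the reporting layer.
DEFAULT_CHX_HOURS <- c(1, 2, 4, 8, 24)
DEFAULT_SIRNA_HOURS <- 48
DEFAULT_SURFACE_TARGETS <- c(R1 = 1800, R2 = 4900, N1 = 68000)

#' The 24-point HUVEC calibration dataset
#'
#' Builds the calibration dataset used to estimate the HUVEC trafficking
#' parameters: eight observations per receptor comprising the absolute
#' surface receptor count (1,800 / 4,900 / 68,000 receptors per cell for
#' VEGFR1 / VEGFR2 / NRP1), the percentage of the receptor on the surface
#' (10 / 51 / 74 %), the whole-cell fold change after Rab4a+Rab11a double
#' knockdown (no detectable change, i.e. 1.0), and a five-point whole-cell
#' fold-change time course under cycloheximide. The published band
#' intensities behind the time courses are not available numerically, so the
#' CHX targets are reconstructed from the measured decay: exponential decay
#' with a 45-minute half-life for VEGFR1, an 82.5-minute half-life for
#' VEGFR2 (midpoint of the reported 75-90 minute range), and no turnover
#' (flat at 1.0) for NRP1.
#'
#' @param chx_hours CHX sampling grid in hours.
#' @param sirna_hours Duration of the simulated knockdown before the
#'   whole-cell measurement, hours.
#' @param half_life_min Named whole-cell CHX half-lives in minutes (`NA` =
#'   stable, fold change 1).
#' @param surface_targets Surface receptor densities, receptors/cell.
#' @param pct_surface Surface percentage of total, per receptor.
#' @return A `calibration_dataset`: data.frame with columns `receptor`,
#'   `type` (`surface_count`, `surface_percent`, `sirna_double_foldchange`,
#'   `chx_foldchange`), `time_h`, `value`, `weight`.
#' @export
huvec_dataset <- function(chx_hours = DEFAULT_CHX_HOURS,
                          sirna_hours = DEFAULT_SIRNA_HOURS,
                          half_life_min = c(R1 = 45, R2 = 82.5, N1 = NA),
                          surface_targets = DEFAULT_SURFACE_TARGETS,
                          pct_surface = c(R1 = 10, R2 = 51, N1 = 74)) {
  rows <- list()
  for (r in RECEPTORS) {
    rows[[length(rows) + 1L]] <- data.frame(
      receptor = r, type = "surface_count", time_h = NA_real_,
      value = surface_targets[[r]], weight = 1
    )
    rows[[length(rows) + 1L]] <- data.frame(
      receptor = r, type = "surface_percent", time_h = NA_real_,
      value = pct_surface[[r]], weight = 1
    )
    rows[[length(rows) + 1L]] <- data.frame(
      receptor = r, type = "sirna_double_foldchange", time_h = sirna_hours,
      value = 1, weight = 1
    )
    hl <- half_life_min[[r]]
    fc <- if (is.na(hl)) rep(1, length(chx_hours)) else 2^(-chx_hours * 60 / hl)
    rows[[length(rows) + 1L]] <- data.frame(
      receptor = r, type = "chx_foldchange", time_h = chx_hours,
      value = fc, weight = 1
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("calibration_dataset", "data.frame")
  out
}

#' Read or write a calibration dataset as CSV
#'
#' Shared schema (`receptor`, `type`, `time_h`, `value`, `weight`) used by
#' both the in-lab dataset builder and the synthetic-data generator.
#'
#' @param dataset A `calibration_dataset`.
#' @param path CSV path.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receptor", "type", "time_h", "value", "weight")
  if (!all(need %in% names(out))) {
    stop("dataset file must have columns: ", paste(need, collapse = ", "))
  }
  class(out) <- c("calibration_dataset", "data.frame")
  out
}

#' Solve the production rates for target surface densities
#'
#' The inner loop of the calibration: given trafficking and coupling rate
#' constants, find the three zeroth-order production rates whose steady
#' state reproduces the target surface receptor densities
#' (stoichiometry-weighted, complexes included).
#'
#' Because every VEGFR1-containing complex traffics at VEGFR1's rates and
#' VEGFR2 never couples to the others, the stoichiometry-weighted
#' compartment totals of VEGFR1 and VEGFR2 obey the three-compartment
#' linear monomer system exactly, coupling or not — so their production
#' rates have the closed form
#' `k_prod = S k_int k_deg / (k_deg + k_rec4 + k_4to11)`. Only NRP1's rate
#' requires a numeric solve (NRP1 riding in VEGFR1 complexes traffics at
#' VEGFR1 rates): a one-dimensional, monotone root-find in log space
#' (secant steps safeguarded by bisection), which reduces to the same
#' closed form when the VEGFR1-NRP1 coupling is off.
#'
#' @param params A [traffic_params()] object (its `k_prod` is ignored).
#' @param surface_targets Named target surface counts (receptors/cell),
#'   nonnegative.
#' @param tol Relative tolerance on the achieved NRP1 surface count.
#' @param network Optional prebuilt network for `params`.
#' @return `params` with `k_prod` replaced by the solved rates.
#' @export
solve_production_rates <- function(params,
                                   surface_targets = DEFAULT_SURFACE_TARGETS,
                                   tol = 1e-8, network = NULL) {
  tgt <- unlist(surface_targets)[RECEPTORS]
  if (anyNA(tgt) || any(tgt < 0)) stop("surface targets must be nonnegative and named R1/R2/N1")
  tr <- params$trafficking
  infeasible <- (tgt > 0) & (tr["k_int", ] <= 0 | tr["k_deg", ] <= 0)
  # NRP1 can still be drained through VEGFR1-carrying complexes
  if (infeasible[["N1"]] && params$kc[["R1N1"]] > 0 && tr["k_deg", "R1"] > 0 &&
      tr["k_int", "N1"] > 0 && tgt[["R1"]] > 0) {
    infeasible[["N1"]] <- FALSE
  }
  if (any(infeasible)) {
    stop("production solve infeasible for ",
         paste(RECEPTORS[infeasible], collapse = ", "),
         ": zero internalization or degradation cannot balance production")
  }

  closed_form <- function(r) {
    tgt[[r]] * tr["k_int", r] * tr["k_deg", r] /
      (tr["k_deg", r] + tr["k_rec4", r] + tr["k_4to11", r])
  }
  params$k_prod[["R1"]] <- if (tgt[["R1"]] > 0) closed_form("R1") else 0
  params$k_prod[["R2"]] <- if (tgt[["R2"]] > 0) closed_form("R2") else 0

  if (tgt[["N1"]] == 0) {
    params$k_prod[["N1"]] <- 0
    return(params)
  }
  uncoupled_n1 <- params$kc[["R1N1"]] <= 0 || tgt[["R1"]] == 0
  if (uncoupled_n1) {
    params$k_prod[["N1"]] <- closed_form("N1")
    return(params)
  }

  network <- if (is.null(network)) expand_reactions(params) else
    update_network_rates(network, params)
  cache <- network$cache
  cache_key <- c(as.vector(tr), params$kc, params$kd, tgt)
  if (!is.null(cache$n1_key) && identical(cache$n1_key, cache_key)) {
    params$k_prod[["N1"]] <- cache$n1_root
    return(params)
  }
  warm_ss <- cache$n1_state
  surface_n1 <- function(kp_n1) {
    params$k_prod[["N1"]] <- kp_n1
    network <<- update_network_rates(network, params)
    ss <- steady_state(params, network = network, x0 = warm_ss)
    warm_ss <<- ss
    receptor_pools(ss)["N1", "SURFACE"]
  }

  # bracket the monotone 1-D problem in log space, then take secant steps
  # safeguarded by bisection; a previous nearby solution (cached on the
  # network) makes the typical re-solve a couple of evaluations
  kp0 <- max(closed_form("N1"), 1e-12 * tgt[["N1"]])
  if (!is.null(cache$n1_root) && is.finite(cache$n1_root) && cache$n1_root > 0) {
    kp0 <- cache$n1_root
  }
  lo <- hi <- log(kp0)
  g_lo <- g_hi <- log(surface_n1(kp0) / tgt[["N1"]])
  if (abs(g_lo) < tol) {
    params$k_prod[["N1"]] <- kp0
    cache$n1_key <- cache_key
    cache$n1_root <- kp0
    cache$n1_state <- warm_ss
    return(params)
  }
  for (i in 1:60) {
    if (g_lo > 0) { lo <- lo - 1; g_lo <- log(surface_n1(exp(lo)) / tgt[["N1"]]) }
    else if (g_hi < 0) { hi <- hi + 1; g_hi <- log(surface_n1(exp(hi)) / tgt[["N1"]]) }
    else break
    if (i == 60) stop("production solve infeasible for N1: cannot bracket the surface target")
  }
  if (g_lo > 0 || g_hi < 0) stop("production solve infeasible for N1: cannot bracket the surface target")
  for (i in 1:200) {
    if (min(abs(g_lo), abs(g_hi)) < tol) break
    u <- if (abs(g_hi - g_lo) > 1e-14) lo - g_lo * (hi - lo) / (g_hi - g_lo) else
      (lo + hi) / 2
    # safeguard: fall back to bisection when secant leaves the bracket
    if (u <= lo || u >= hi) u <- (lo + hi) / 2
    g <- log(surface_n1(exp(u)) / tgt[["N1"]])
    if (g > 0) { hi <- u; g_hi <- g } else { lo <- u; g_lo <- g }
    if (hi - lo < 1e-13) break
  }
  u_best <- if (abs(g_lo) < abs(g_hi)) lo else hi
  if (min(abs(g_lo), abs(g_hi)) > 1e-4) {
    stop("production-rate solve did not converge for N1")
  }
  params$k_prod[["N1"]] <- exp(u_best)
  cache$n1_key <- cache_key
  cache$n1_root <- exp(u_best)
  cache$n1_state <- warm_ss
  params
}

#' Model predictions matched to a calibration dataset
#'
#' Runs the full simulation pipeline for one trafficking parameter set:
#' inner production solve against the surface-count rows, baseline steady
#' state, CHX chase (all production rates to zero) and Rab4a+Rab11a double
#' knockdown protocols, aggregation, and normalization to the untreated
#' steady state. Returns one prediction per dataset row, in row order.
#'
#' @param params A [traffic_params()] object; `k_prod` is re-solved against
#'   the dataset's `surface_count` rows.
#' @param dataset A `calibration_dataset`.
#' @param network Optional prebuilt network.
#' @return List with `predicted` (numeric, one per row), `params` (with the
#'   solved production rates) and `steady` (the baseline steady state).
#' @export
predict_dataset <- function(params, dataset, network = NULL) {
  if (is.null(network)) network <- expand_reactions(params)
  sc <- dataset[dataset$type == "surface_count", ]
  tgt <- DEFAULT_SURFACE_TARGETS
  if (nrow(sc) > 0) tgt[sc$receptor] <- sc$value
  params <- solve_production_rates(params, surface_targets = tgt,
                                   network = network)
  network <- update_network_rates(network, params)
  ss <- steady_state(params, network = network)
  agg0 <- aggregate_state(ss)
  base_total <- stats::setNames(agg0$total, agg0$receptor)
  base_surface <- stats::setNames(agg0$surface, agg0$receptor)
  pct <- stats::setNames(agg0$pct_surface, agg0$receptor)

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
    traj <- simulate_protocol(params, ss,
                              times = c(0, sort(sir_hours) * 3600),
                              perturbation_spec = perturbation("SIRNA_DOUBLE"),
                              network = network)
    sir_fc <- normalize_to_control(trajectory_totals(traj))
    rownames(sir_fc) <- as.character(traj$time / 3600)
  }

  predicted <- numeric(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    r <- dataset$receptor[i]
    predicted[i] <- switch(dataset$type[i],
      surface_count = base_surface[[r]],
      surface_percent = pct[[r]],
      sirna_double_foldchange = sir_fc[as.character(dataset$time_h[i]), r],
      chx_foldchange = chx_fc[as.character(dataset$time_h[i]), r],
      stop("unknown observation type: ", dataset$type[i])
    )
  }
  list(predicted = predicted, params = params, steady = ss)
}

#' Sum-of-squares calibration cost
#'
#' Cost of a trafficking parameter set against a calibration dataset: the sum
#' over observations of squared weighted relative residuals,
#' `sum(w * ((sim - obs) / obs)^2)`. Relative residuals put receptor counts
#' (10^3-10^4 molecules) and fold changes (order 1) on a comparable scale.
#' Simulation failures (infeasible steady states) propagate as a large finite
#' penalty rather than an error so that optimization can continue.
#'
#' @inheritParams predict_dataset
#' @return Scalar cost (0 for a perfect fit).
#' @export
traffic_cost <- function(params, dataset, network = NULL) {
  r <- traffic_residuals(params, dataset, network = network)
  sum(r^2)
}

# Weighted relative residual vector; large finite penalty on failure. The
# denominator carries a detection floor (default 0.01, i.e. 1% of the
# control band for fold-change observations): band densitometry cannot
# quantify below about a percent of the loading control, so relative error
# against a target like 2^-32 is physically meaningless and would otherwise
# dominate the cost with cliffs that trap the optimizer.
traffic_residuals <- function(params, dataset, network = NULL,
                              penalty = 1e6, floor = 0.01) {
  pred <- tryCatch(predict_dataset(params, dataset, network = network),
                   error = function(e) NULL)
  if (is.null(pred) || anyNA(pred$predicted)) {
    return(rep(penalty, nrow(dataset)))
  }
  denom <- pmax(abs(dataset$value), floor)
  res <- sqrt(dataset$weight) * (pred$predicted - dataset$value) / denom
  res[!is.finite(res)] <- penalty
  pmin(pmax(res, -penalty), penalty)
}

#' Multistart bounded Levenberg-Marquardt calibration
#'
#' Fits the 15 trafficking rate constants to a calibration dataset by
#' repeated bounded Levenberg-Marquardt least squares from random starting
#' points. Starting values are drawn log-uniformly within the bounds
#' (default `[1e-6, 1e-1]` s^-1) and the optimization runs, by default, in
#' log10 parameter space with box constraints at the bounds (rate constants
#' span five orders of magnitude, and log coordinates let the optimizer
#' traverse them); `par_space = "linear"` runs in natural units instead.
#' The three production rates are not free
#' parameters: they are re-solved inside every residual evaluation so that
#' the steady state matches the measured surface densities (the "inner
#' production loop").
#'
#' @param dataset A `calibration_dataset`.
#' @param n_starts Number of random starts (the full calibration uses 100).
#' @param bounds Length-2 lower/upper bounds on every trafficking rate
#'   constant, s^-1.
#' @param seed Integer seed; the ensemble is fully reproducible given
#'   (dataset, n_starts, seed).
#' @param params_template Parameter set providing coupling constants and
#'   membrane areas (trafficking entries are overwritten per start).
#' @param start_values Optional matrix (n_starts x 15) of explicit starting
#'   values overriding the random draw; column order as
#'   [params_to_vector()].
#' @param maxiter Maximum LM iterations per start.
#' @param verbose Print per-start progress.
#' @return A `fit_ensemble`: list of per-start results (`initial`,
#'   `trafficking`, `k_prod`, `cost`, `converged`, `info`) plus the dataset
#'   and settings.
#' @export
multistart_fit <- function(dataset, n_starts = 100,
                           bounds = TRAFFIC_BOUNDS, seed = 1,
                           params_template = NULL, start_values = NULL,
                           maxiter = 500, verbose = FALSE,
                           par_space = c("log10", "linear")) {
  stopifnot(n_starts >= 1)
  par_space <- match.arg(par_space)
  to_opt <- if (par_space == "log10") log10 else identity
  from_opt <- if (par_space == "log10") function(x) 10^x else identity
  if (is.null(params_template)) {
    params_template <- traffic_params(matrix(1e-3, 5, 3))
  }
  lb <- bounds[[1]]; ub <- bounds[[2]]
  set.seed(seed)
  n_par <- 15L
  par_names <- as.vector(outer(TRAFFIC_PROCESSES, RECEPTORS, paste, sep = "."))
  starts <- if (is.null(start_values)) {
    # log-uniform draws within the bounds
    matrix(10^stats::runif(n_starts * n_par, log10(lb), log10(ub)),
           nrow = n_starts, dimnames = list(NULL, par_names))
  } else {
    m <- as.matrix(start_values)
    colnames(m) <- par_names
    m
  }

  network <- expand_reactions(params_template)
  resid_fn <- function(par) {
    p <- params_template
    p$trafficking[] <- from_opt(par)
    traffic_residuals(p, dataset, network = network)
  }

  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    p0 <- starts[s, ]
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = to_opt(p0), lower = rep(to_opt(lb), n_par),
        upper = rep(to_opt(ub), n_par),
        fn = resid_fn,
        # epsfcn well above the ODE/steady-state solver noise (~1e-8
        # relative): finite-difference steps of ~1e-3 of a log10 parameter
        # give clean Jacobians; the library default would difference inside
        # the noise floor
        # maxfev bounds the worst-case wall time of a start; successful
        # runs on this problem converge within ~100 iterations (~1700
        # evaluations)
        control = minpack.lm::nls.lm.control(
          maxiter = maxiter, ftol = 1e-10, ptol = 1e-12, maxfev = 4000,
          epsfcn = 1e-6
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      fits[[s]] <- list(initial = p0, converged = FALSE,
                        message = "optimizer error")
      next
    }
    p_hat <- params_template
    p_hat$trafficking[] <- from_opt(fit$par)
    k_prod <- tryCatch({
      solved <- predict_dataset(p_hat, dataset, network = network)$params
      solved$k_prod
    }, error = function(e) rep(NA_real_, 3))
    cost <- sum(fit$fvec^2)
    fits[[s]] <- list(
      initial = p0,
      trafficking = trafficking_from_vector(
        stats::setNames(unname(from_opt(fit$par)), par_names)),
      k_prod = k_prod,
      cost = cost,
      converged = is.finite(cost) && fit$info %in% 1:4 && !anyNA(k_prod),
      info = fit$info,
      niter = fit$niter
    )
    if (verbose) {
      message(sprintf("start %d/%d: cost %.4g (info %d, %d iter)",
                      s, n_starts, cost, fit$info, fit$niter))
    }
  }
  structure(
    list(fits = fits, dataset = dataset, bounds = bounds, seed = seed,
         params_template = params_template),
    class = "fit_ensemble"
  )
}

#' @export
print.fit_ensemble <- function(x, ...) {
  costs <- vapply(x$fits, function(f) if (is.null(f$cost)) NA_real_ else f$cost, 0)
  conv <- vapply(x$fits, function(f) isTRUE(f$converged), TRUE)
  cat("Multistart fit ensemble:", length(x$fits), "starts,",
      sum(conv), "converged\n")
  cat("cost: min", signif(min(costs, na.rm = TRUE), 4),
      "median", signif(stats::median(costs[conv]), 4), "\n")
  invisible(x)
}

converged_fits <- function(ensemble, cost_threshold = Inf) {
  Filter(function(f) isTRUE(f$converged) && is.finite(f$cost) &&
           f$cost <= cost_threshold, ensemble$fits)
}

# Default notion of a *successful* optimization: converged and actually
# reproducing the data. With ~24 relative-residual observations and
# blot-replicate noise around 20%, a good fit has cost of order
# 24 * 0.2^2 ~ 1; runs stuck in distant local minima (costs 10-10^9)
# carry no information about the parameters. The floor at 3x the best cost
# keeps the definition usable for noisier datasets where even the optimum
# exceeds 1.
success_threshold <- function(ensemble) {
  costs <- vapply(ensemble$fits,
                  function(f) if (is.null(f$cost)) Inf else f$cost, 0)
  max(1, 3 * min(costs, na.rm = TRUE))
}

#' Consensus parameter set from a fit ensemble
#'
#' Per-parameter summary over the converged fits (median in log10 space by
#' default, or the geometric mean), with the production rates re-solved for
#' the consensus trafficking values so that the calibration surface targets
#' are reproduced exactly.
#'
#' @param ensemble A `fit_ensemble` from [multistart_fit()].
#' @param center `"median"` (log-space median) or `"geomean"`.
#' @param cost_threshold Only *successful* optimizations — converged runs
#'   whose final cost shows the data are reproduced — enter the summary.
#'   The default, `max(1, 3 * best cost)`, corresponds to an average
#'   relative residual around 20% over the 24 observations (the scale of
#'   replicate blot variability); runs stranded in distant local minima
#'   carry no parameter information. Pass `Inf` to summarize every
#'   converged run.
#' @return List with `params` (consensus `traffic_params`), `summary`
#'   (data.frame of per-parameter median and 5th/95th percentiles, s^-1) and
#'   `n_converged`.
#' @export
summarize_fits <- function(ensemble, center = c("median", "geomean"),
                           cost_threshold = NULL) {
  center <- match.arg(center)
  if (is.null(cost_threshold)) cost_threshold <- success_threshold(ensemble)
  fits <- converged_fits(ensemble, cost_threshold)
  if (length(fits) == 0) stop("no successful fits in ensemble")
  logmat <- t(vapply(fits, function(f) log10(as.vector(f$trafficking)),
                     numeric(15)))
  par_names <- as.vector(outer(TRAFFIC_PROCESSES, RECEPTORS, paste, sep = "."))
  colnames(logmat) <- par_names
  mid <- if (center == "median") apply(logmat, 2, stats::median) else
    colMeans(logmat)
  qs <- apply(logmat, 2, stats::quantile, probs = c(0.05, 0.95))
  p <- ensemble$params_template
  p$trafficking[] <- 10^mid
  sc <- ensemble$dataset[ensemble$dataset$type == "surface_count", ]
  tgt <- DEFAULT_SURFACE_TARGETS
  if (nrow(sc) > 0) tgt[sc$receptor] <- sc$value
  p <- solve_production_rates(p, surface_targets = tgt)
  list(
    params = p,
    cost_threshold = cost_threshold,
    summary = data.frame(
      parameter = par_names,
      median = 10^apply(logmat, 2, stats::median),
      geomean = 10^colMeans(logmat),
      q05 = 10^qs[1, ],
      q95 = 10^qs[2, ],
      row.names = NULL
    ),
    n_converged = length(fits)
  )
}

#' Correlation between initial guesses and optimized values
#'
#' A diagnostic of parameter identifiability: low correlation between where
#' an optimization started and where it finished indicates that the data,
#' not the starting point, determines the estimate.
#'
#' @param ensemble A `fit_ensemble` with at least 3 successful fits.
#' @param cost_threshold Success filter, as in [summarize_fits()].
#' @return data.frame with `parameter` and `correlation` (Pearson, on log10
#'   values; `NA` where the optimized values are numerically constant across
#'   starts, flagged in `degenerate`).
#' @export
initial_final_correlation <- function(ensemble, cost_threshold = NULL) {
  if (is.null(cost_threshold)) cost_threshold <- success_threshold(ensemble)
  fits <- converged_fits(ensemble, cost_threshold)
  if (length(fits) < 3) stop("need at least 3 converged fits")
  par_names <- as.vector(outer(TRAFFIC_PROCESSES, RECEPTORS, paste, sep = "."))
  init <- t(vapply(fits, function(f) log10(f$initial[par_names]), numeric(15)))
  final <- t(vapply(fits, function(f) log10(as.vector(f$trafficking)), numeric(15)))
  cors <- numeric(15)
  degen <- logical(15)
  for (j in 1:15) {
    if (stats::sd(final[, j]) < 1e-12 || stats::sd(init[, j]) < 1e-12) {
      cors[j] <- NA_real_
      degen[j] <- TRUE
    } else {
      cors[j] <- stats::cor(init[, j], final[, j])
    }
  }
  data.frame(parameter = par_names, correlation = cors, degenerate = degen)
}
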