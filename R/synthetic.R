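# Synthetic pseudo-western data generator -------------------------------------

#' Draw a ground-truth parameter set
#'
#' Draws the 15 trafficking rate constants log-uniformly within the
#' calibration bounds and solves the production rates so that the
#' steady-state surface densities hit plausible targets (the measured HUVEC
#' values by default). Draws for which the production solve is infeasible
#' are rejected and redrawn, so the returned truth always admits a steady
#' state; the procedure is fully determined by the seed.
#'
#' @param seed Integer seed.
#' @param surface_targets Surface densities the truth must reproduce
#'   (receptors/cell).
#' @param bounds Lower/upper bounds for the log-uniform draw, s^-1.
#' @param params_template Coupling constants and membrane areas for the
#'   truth (defaults to the standard configuration).
#' @return A `traffic_params` object with attribute `seed`.
#' @export
draw_ground_truth <- function(seed,
                              surface_targets = DEFAULT_SURFACE_TARGETS,
                              bounds = TRAFFIC_BOUNDS,
                              params_template = NULL) {
  if (is.null(params_template)) {
    params_template <- traffic_params(matrix(1e-3, 5, 3))
  }
  set.seed(seed)
  lb <- log10(bounds[[1]]); ub <- log10(bounds[[2]])
  for (attempt in 1:50) {
    p <- params_template
    p$trafficking[] <- 10^stats::runif(15, lb, ub)
    solved <- tryCatch(
      solve_production_rates(p, surface_targets = surface_targets),
      error = function(e) NULL
    )
    if (!is.null(solved)) {
      attr(solved, "seed") <- seed
      return(solved)
    }
  }
  stop("could not draw a feasible ground truth in 50 attempts")
}

#' Multiplicative log-normal measurement noise
#'
#' Emulates the variability of western-blot band quantification: strictly
#' positive, roughly constant coefficient of variation. Noise factors have
#' mean 1 and coefficient of variation `cv`; `cv = 0` returns the values
#' unchanged.
#'
#' @param n Number of factors.
#' @param cv Coefficient of variation (>= 0).
#' @return Numeric vector of `n` noise factors.
#' @export
lognormal_noise <- function(n, cv) {
  stopifnot(cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic calibration dataset from a known truth
#'
#' Runs the full measurement pipeline on the ground-truth parameters --
#' steady state, biotin-split surface/total readouts, CHX chase, Rab4a+11a
#' double knockdown -- and overwrites the values of a template dataset with
#' the simulated measurements times multiplicative log-normal noise. The
#' 24-row structure (8 observations per receptor) is preserved, so the
#' result feeds directly into [multistart_fit()] for parameter-recovery
#' experiments.
#'
#' @param truth A `traffic_params` ground truth (e.g. [draw_ground_truth()]).
#' @param cv Noise coefficient of variation (0.15 default emulates replicate
#'   blot densitometry; 0 gives noiseless model predictions).
#' @param seed Seed for the noise draw.
#' @param template Dataset defining the protocol structure (defaults to the
#'   in-lab design: [huvec_dataset()]).
#' @return A `calibration_dataset` with attribute `truth`.
#' @export
generate_measurements <- function(truth, cv = 0.15, seed = 1,
                                  template = huvec_dataset()) {
  network <- expand_reactions(truth)
  # noiseless predictions, but with surface counts taken from the truth's
  # own steady state rather than re-solved production
  ss <- steady_state(truth, network = network)
  pred <- predict_dataset_fixed_production(truth, template, network, ss)
  set.seed(seed)
  noise <- lognormal_noise(nrow(template), cv)
  out <- template
  out$value <- pred * noise
  attr(out, "truth") <- truth
  attr(out, "cv") <- cv
  attr(out, "seed") <- seed
  out
}

#' Simulated biotin-label surface/internal split
#'
#' Emulates the biotin labeling assay: surface receptors are captured in the
#' eluate and internal receptors flow through, with both fractions
#' resuspended in equal volumes so band intensities are proportional to the
#' pools. Noise is applied per band (surface and internal independently),
#' as in densitometry of separate lanes.
#'
#' @param truth A `traffic_params` object.
#' @param cv Band noise coefficient of variation.
#' @param seed Noise seed.
#' @return data.frame with columns `receptor`, `surface`, `internal`,
#'   `total`, `pct_surface`.
#' @export
generate_biotin_split <- function(truth, cv = 0.15, seed = 1) {
  ss <- steady_state(truth)
  pools <- receptor_pools(ss)
  set.seed(seed)
  surface <- pools[, "SURFACE"] * lognormal_noise(3, cv)
  internal <- (pools[, "RAB4"] + pools[, "RAB11"]) * lognormal_noise(3, cv)
  data.frame(
    receptor = RECEPTORS,
    surface = surface,
    internal = internal,
    total = surface + internal,
    pct_surface = 100 * surface / (surface + internal),
    row.names = NULL
  )
}
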