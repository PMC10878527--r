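# Transport-rate analysis, equilibrium coupling, CHQ inhibition estimate -----

#' Overall transport rates (flux table)
#'
#' The overall rate of each trafficking process is its rate constant
#' multiplied by the pool it acts on (stoichiometry-weighted receptors per
#' cell), giving receptors cell^-1 s^-1. At steady state the net rate for
#' each live compartment is close to zero: internalization balances
#' synthesis plus recycling at the surface; inflow from Rab4a balances
#' recycling at Rab11a; internalization balances degradation plus recycling
#' at Rab4a.
#'
#' @param params A [traffic_params()] object.
#' @param state Model state (defaults to the steady state of `params`).
#' @return A `flux_table`: data.frame with columns `receptor`, `process`,
#'   `from`, `to`, `rate_per_s`, plus attribute `net`, the per-compartment
#'   net rates (receptors/cell/s) by receptor.
#' @export
compute_fluxes <- function(params, state = NULL) {
  network <- expand_reactions(params)
  if (is.null(state)) state <- steady_state(params, network = network)
  rates <- reaction_rates(state, network)
  rx <- network$reactions
  traffic_classes <- c("production", "internalization", "recycle4",
                       "transfer4to11", "recycle11", "degradation")
  rows <- list()
  for (r in RECEPTORS) {
    for (cl in traffic_classes) {
      sel <- rx$class == cl
      if (cl == "production") {
        sel <- sel & rx$rate_constant_name == paste0("k_prod.", r)
        w <- rep(1, sum(sel))
      } else {
        # weight each reaction by the copies of receptor r in its complex
        cx <- sub(" .*", "", rx$reactants[sel])
        w <- COMPLEX_COMPOSITION[r, cx]
      }
      flux <- sum(w * rates[sel])
      from <- switch(cl, production = "", internalization = "SURFACE",
                     recycle4 = "RAB4", transfer4to11 = "RAB4",
                     recycle11 = "RAB11", degradation = "RAB4")
      to <- switch(cl, production = "SURFACE", internalization = "RAB4",
                   recycle4 = "SURFACE", transfer4to11 = "RAB11",
                   recycle11 = "SURFACE", degradation = "DEGRADED")
      rows[[length(rows) + 1L]] <- data.frame(
        receptor = r, process = cl, from = from, to = to, rate_per_s = flux
      )
    }
  }
  out <- do.call(rbind, rows)
  # net rate per live compartment and receptor (coupling moves no receptor
  # mass between compartments, so trafficking fluxes fully determine these)
  net <- matrix(0, 3, 3, dimnames = list(RECEPTORS, LIVE_COMPARTMENTS))
  for (i in seq_len(nrow(out))) {
    if (out$from[i] %in% LIVE_COMPARTMENTS) {
      net[out$receptor[i], out$from[i]] <-
        net[out$receptor[i], out$from[i]] - out$rate_per_s[i]
    }
    if (out$to[i] %in% LIVE_COMPARTMENTS) {
      net[out$receptor[i], out$to[i]] <-
        net[out$receptor[i], out$to[i]] + out$rate_per_s[i]
    }
  }
  structure(out, net = net, class = c("flux_table", "data.frame"))
}

#' Write a flux table as CSV
#' @param fluxes A `flux_table` from [compute_fluxes()].
#' @param path CSV path.
#' @export
write_flux_csv <- function(fluxes, path) {
  utils::write.csv(as.data.frame(fluxes), path, row.names = FALSE)
  invisible(path)
}

#' Surface residence half-life
#'
#' Time for half of a surface receptor cohort to be internalized:
#' `ln(2) / k_int`.
#'
#' @param k_int Internalization rate constant, s^-1 (> 0).
#' @return Half-life in seconds.
#' @export
surface_residence_half_life <- function(k_int) {
  if (any(k_int <= 0)) stop("k_int must be > 0")
  log(2) / k_int
}

#' Recycling-to-degradation rate-constant ratio
#'
#' Ratio of the combined recycling rate constants (both pathways out of the
#' early endosome: direct Rab4a recycling plus transfer to Rab11a, which
#' recycles everything it receives at steady state) to the degradation rate
#' constant: `(k_rec4 + k_4to11) / k_deg`. A ratio of r means roughly r
#' receptors are recycled for every receptor degraded.
#'
#' @param params A [traffic_params()] object.
#' @param receptor `"R1"`, `"R2"` or `"N1"`.
#' @return Dimensionless ratio.
#' @export
recycling_degradation_ratio <- function(params, receptor = "R1") {
  receptor <- match.arg(receptor, RECEPTORS)
  tr <- params$trafficking
  if (tr["k_deg", receptor] <= 0) stop("k_deg must be > 0")
  (tr["k_rec4", receptor] + tr["k_4to11", receptor]) / tr["k_deg", receptor]
}

#' Equilibrium homodimer fraction
#'
#' Closed-form equilibrium of reversible homodimerization with forward rate
#' `kc * M^2` and dissociation `kd * D`, under the conservation
#' `M + 2 D = R_T`: the free monomer level is the positive root of
#' `2 (kc/kd) M^2 + M - R_T = 0` and the dimer fraction is `2 D / R_T`.
#'
#' @param R_T Total receptor level (per-cell or per-area units, matching
#'   `kc`).
#' @param kc Coupling rate constant, (molecules)^-1 s^-1 in the same units
#'   as `R_T`.
#' @param kd Uncoupling rate constant, s^-1 (> 0).
#' @return Fraction of receptors in dimers, in `[0, 1]`.
#' @export
equilibrium_dimer_fraction <- function(R_T, kc, kd) {
  stopifnot(R_T >= 0, kc >= 0, kd > 0)
  if (R_T == 0 || kc == 0) return(0)
  c1 <- kc / kd
  m <- (-1 + sqrt(1 + 8 * c1 * R_T)) / (4 * c1)
  (R_T - m) / R_T
}

#' Equilibrium VEGFR1-NRP1 coupling (full complex spectrum)
#'
#' Numerically solves the coupled equilibrium of all VEGFR1/NRP1 species
#' (monomers, VEGFR1 homodimer, and the three VEGFR1-NRP1 complexes) for
#' given totals, returning species levels and summary fractions. With
#' `kc_R1R1 = 0` this reduces to the closed-form 1:1 binding equilibrium;
#' with homodimerization on it covers 2:2 binding, from which an effective
#' affinity `K_d_eff` (the free NRP1 level at which half of VEGFR1 is in
#' NRP1-bound complexes) can be compared against the single-site
#' `K_d = kd/kc`.
#'
#' @param R_T,N_T Total VEGFR1 and NRP1 levels (#/cell).
#' @param kc_R1N1,kd_R1N1 VEGFR1-NRP1 coupling/uncoupling rate constants
#'   ((#/cell)^-1 s^-1 and s^-1).
#' @param kc_R1R1,kd_R1R1 VEGFR1 homodimerization constants (defaults 0 =
#'   1:1 binding only).
#' @return List with `species` (named levels), `frac_R1_bound` (fraction of
#'   all VEGFR1 in NRP1-containing complexes), `frac_N1_bound`, `K_d` and
#'   `K_d_eff` (#/cell).
#' @export
equilibrium_r1n1 <- function(R_T, N_T, kc_R1N1, kd_R1N1,
                             kc_R1R1 = 0, kd_R1R1 = 0.01) {
  stopifnot(R_T >= 0, N_T >= 0, kc_R1N1 >= 0, kd_R1N1 > 0)
  cx <- couple_equilibrium(
    c(R1 = R_T, R2 = 0, N1 = N_T),
    kc_cell = c(R1R1 = kc_R1R1, R2R2 = 0, R1N1 = kc_R1N1),
    kd = c(R1R1 = kd_R1R1, R2R2 = 0.01, R1N1 = kd_R1N1)
  )
  r1_bound <- cx[["R1N1"]] + 2 * cx[["R1R1N1"]] + 2 * cx[["R1R1N1N1"]]
  n1_bound <- cx[["R1N1"]] + cx[["R1R1N1"]] + 2 * cx[["R1R1N1N1"]]
  frac_r1 <- if (R_T > 0) r1_bound / R_T else 0
  # half-occupancy free-NRP1 level: N1-binding sites on VEGFR1 are
  # independent with per-site K_d, so half occupancy of sites occurs at
  # free N1 = K_d regardless of dimerization; report it numerically from
  # occupied vs free sites
  sites_occ <- cx[["R1N1"]] + cx[["R1R1N1"]] + 2 * cx[["R1R1N1N1"]]
  sites_free <- cx[["R1"]] + 2 * cx[["R1R1"]] + cx[["R1R1N1"]]
  kd_eff <- if (sites_occ > 0) cx[["N1"]] * sites_free / sites_occ else NA_real_
  list(
    species = cx,
    frac_R1_bound = frac_r1,
    frac_N1_bound = if (N_T > 0) n1_bound / N_T else 0,
    K_d = kd_R1N1 / kc_R1N1,
    K_d_eff = kd_eff
  )
}

#' Whole-cell half-life from a protocol trajectory
#'
#' Finds the time at which the whole-cell (surface + internal) level of a
#' receptor falls to half its initial value, by log-linear interpolation of
#' the trajectory.
#'
#' @param traj A `traffic_trajectory` (e.g. a CHX chase).
#' @param receptor `"R1"`, `"R2"` or `"N1"`.
#' @return Half-life in seconds (`NA` if the level never falls below half).
#' @export
whole_cell_half_life <- function(traj, receptor = "R1") {
  receptor <- match.arg(receptor, RECEPTORS)
  tot <- trajectory_totals(traj)[, receptor]
  target <- tot[1] / 2
  below <- which(tot <= target)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(0)
  # log-linear interpolation between bracketing points
  t1 <- traj$time[i - 1]; t2 <- traj$time[i]
  y1 <- log(tot[i - 1]); y2 <- log(max(tot[i], 1e-300))
  t1 + (log(target) - y1) * (t2 - t1) / (y2 - y1)
}

#' Estimate the chloroquine inhibition fraction
#'
#' Given a measured whole-cell fold-change series under chloroquine (CHQ),
#' estimates the single scalar f by which CHQ reduces the degradation rate
#' constants (`k_deg -> (1 - f) k_deg`), by least squares between the series
#' and the simulated CHQ protocol, holding all other parameters fixed.
#'
#' @param times_h Measurement times, hours (control at time zero is implied
#'   and must not be included).
#' @param foldchange Whole-cell fold changes relative to untreated, same
#'   length as `times_h`.
#' @param params Calibrated parameter set.
#' @param receptor Receptor whose whole-cell series is fitted (default
#'   VEGFR1, the receptor that accumulates under CHQ).
#' @return List with `f` (in `[0, 1]`), `sse`, `fitted` (simulated fold
#'   changes at `times_h`), and `clipped` (`TRUE` when the series lies below
#'   1 so that no inhibition is consistent and f is clipped at 0).
#' @export
estimate_chq_inhibition <- function(times_h, foldchange, params,
                                    receptor = "R1") {
  receptor <- match.arg(receptor, RECEPTORS)
  stopifnot(length(times_h) == length(foldchange), all(times_h > 0))
  if (is.unsorted(times_h, strictly = TRUE)) {
    stop("'times_h' must be strictly increasing")
  }
  network <- expand_reactions(params)
  ss <- steady_state(params, network = network)
  times <- c(0, times_h * 3600)

  sim_fc <- function(f) {
    traj <- simulate_protocol(params, ss, times = times,
                              perturbation_spec = perturbation("CHQ", chq_fraction = f),
                              network = network)
    normalize_to_control(trajectory_totals(traj))[-1, receptor]
  }
  sse_of <- function(f) sum((sim_fc(f) - foldchange)^2)
  opt <- stats::optimize(sse_of, interval = c(0, 1), tol = 1e-6)
  f_hat <- opt$minimum
  # snap to the boundaries when they fit at least as well (optimize() never
  # returns an exact endpoint)
  for (b in c(0, 1)) if (sse_of(b) <= opt$objective + 1e-12) f_hat <- b
  clipped <- all(foldchange <= 1) && f_hat == 0
  list(f = f_hat, sse = sse_of(f_hat), fitted = sim_fc(f_hat),
       clipped = clipped)
}
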