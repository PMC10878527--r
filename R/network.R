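# Molecular state space and rule-expanded reaction network ---------------------

# The 8 molecules / molecular complexes and their receptor stoichiometry.
# VEGFR2 never couples to VEGFR1 or NRP1 in the absence of ligand, and an NRP1
# can only be carried by a VEGFR1, so these are the only valid compositions.
COMPLEXES <- c("R1", "R2", "N1", "R1R1", "R2R2", "R1N1", "R1R1N1", "R1R1N1N1")

# receptors x complexes copy-number matrix
COMPLEX_COMPOSITION <- matrix(
  c(
    # R1 R2 N1 R1R1 R2R2 R1N1 R1R1N1 R1R1N1N1
    1, 0, 0, 2, 0, 1, 2, 2, # R1
    0, 1, 0, 0, 2, 0, 0, 0, # R2
    0, 0, 1, 0, 0, 1, 1, 2  # N1
  ),
  nrow = 3, byrow = TRUE, dimnames = list(RECEPTORS, COMPLEXES)
)

# Which receptor's trafficking rate constants a complex obeys: anything
# containing VEGFR1 (including VEGFR1-NRP1 complexes) traffics with VEGFR1's
# constants; VEGFR2-only species with VEGFR2's; the NRP1 monomer with NRP1's.
TRAFFIC_CLASS_OF_COMPLEX <- c(
  R1 = "R1", R2 = "R2", N1 = "N1", R1R1 = "R1", R2R2 = "R2",
  R1N1 = "R1", R1R1N1 = "R1", R1R1N1N1 = "R1"
)

#' Enumerate the model state entries
#'
#' The model state has 32 entries: each of the 8 molecules or molecular
#' complexes in each of the 3 live compartments (cell surface, Rab4a/5a early
#' endosomes, Rab11a recycling endosomes), plus a cumulative degraded pool per
#' complex. Ordering is compartment-major with a fixed complex order
#' (`R1, R2, N1, R1R1, R2R2, R1N1, R1R1N1, R1R1N1N1`); every state vector,
#' trajectory column and I/O table in the package uses these labels.
#'
#' @param include_complexes If `FALSE`, enumerate only the monomer species
#'   (the state space of the model with all coupling rules removed; 12
#'   entries).
#' @return A data.frame with columns `index`, `label`, `compartment`,
#'   `complex`.
#' @export
enumerate_species <- function(include_complexes = TRUE) {
  cx <- if (include_complexes) COMPLEXES else RECEPTORS
  comp <- c(LIVE_COMPARTMENTS, "DEGRADED")
  out <- expand.grid(complex = cx, compartment = comp,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("compartment", "complex")]
  out$label <- paste(out$compartment, out$complex, sep = ".")
  out$index <- seq_len(nrow(out))
  out[, c("index", "label", "compartment", "complex")]
}

state_index <- function(compartment, complex) {
  match(paste(compartment, complex, sep = "."), SPECIES_LABELS)
}

SPECIES_LABELS <- paste(
  rep(c(LIVE_COMPARTMENTS, "DEGRADED"), each = length(COMPLEXES)),
  COMPLEXES, sep = "."
)

#' An all-zero model state
#'
#' @return Named numeric vector of length 32 (all species in all compartments
#'   plus the cumulative degraded pools), receptors-or-complexes per cell.
#' @export
empty_state <- function() {
  stats::setNames(numeric(length(SPECIES_LABELS)), SPECIES_LABELS)
}

# Coupling rule table: 7 reversible rules, instantiated per live compartment.
# `fw_factor` is the statistical factor on the coupling direction, `bw_factor`
# on the uncoupling direction, both relative to the shared base constants of
# the bond type. Conventions: homodimerization of identical species runs at
# kc * [M]^2 (so kc is half the pairwise microscopic association rate) and
# dissociation at kd * [D], giving [D] = (kc/kd) [M]^2. Consequences for the
# mixed species, chosen for microscopic consistency (every assembly route to
# a complex yields the same equilibrium level, i.e. detailed balance holds):
# * a free VEGFR1 binding the vacant dimerization site of R1N1 sees one
#   specific partner, i.e. the full pairwise rate 2*kc -> factor 2 (rule 4);
# * two R1N1 dimerizing are an identical pair -> kc * [R1N1]^2, factor 1;
# * NRP1 binding a VEGFR1 dimer has two free sites -> factor 2 (rule 6),
#   and one free site on R1R1N1 -> factor 1 (rule 7);
# * the doubly occupied complex has two dissociable NRP1 -> backward factor
#   2 on rule 7; each R1-R1 bond dissociates with factor 1.
coupling_rules <- function() {
  data.frame(
    rule = 1:7,
    reactant1 = c("R1", "R2", "R1", "R1N1", "R1N1", "R1R1", "R1R1N1"),
    reactant2 = c("R1", "R2", "N1", "R1", "R1N1", "N1", "N1"),
    product = c("R1R1", "R2R2", "R1N1", "R1R1N1", "R1R1N1N1", "R1R1N1", "R1R1N1N1"),
    pair = c("R1R1", "R2R2", "R1N1", "R1R1", "R1R1", "R1N1", "R1N1"),
    fw_factor = c(1, 1, 1, 2, 1, 2, 1),
    bw_factor = c(1, 1, 1, 1, 1, 1, 2),
    stringsAsFactors = FALSE
  )
}

#' Expand the rule set into the concrete mass-action reaction network
#'
#' Expands production, trafficking/degradation and coupling rules into the 85
#' individual reactions of the model: 3 production reactions (one surface
#' monomer each), 40 trafficking/degradation reactions (5 first-order
#' processes applied to each of the 8 complexes), 21 coupling and 21
#' uncoupling reactions (7 reversible rules in each of the 3 live
#' compartments). Coupling rate constants are converted from their base units
#' to per-cell units by dividing by the membrane area of the compartment in
#' which the reaction occurs.
#'
#' @param params A [traffic_params()] object.
#' @return An object of class `traffic_network`: a list with the reaction
#'   table (`$reactions`), the species table (`$species`) and precomputed
#'   stoichiometry/rate-law arrays used by [rhs()] and the integrator.
#' @export
expand_reactions <- function(params) {
  stopifnot(inherits(params, "traffic_params"))
  if (any(params$areas <= 0)) stop("membrane areas must be strictly positive")

  rx <- list()
  add <- function(class, compartment, reactants, products, rate_name,
                  factor, k, r_idx, p_idx, p_stoich) {
    rx[[length(rx) + 1L]] <<- list(
      class = class, compartment = compartment,
      reactants = paste(reactants, collapse = " + "),
      products = paste(products, collapse = " + "),
      rate_constant_name = rate_name, factor = factor, k = k,
      r_idx = r_idx, p_idx = p_idx, p_stoich = p_stoich
    )
  }

  # 3 production reactions: zeroth order, into surface monomers
  for (r in RECEPTORS) {
    add("production", "SURFACE", character(), r,
        paste0("k_prod.", r), 1, params$k_prod[[r]],
        integer(), state_index("SURFACE", r), 1)
  }

  # 40 trafficking/degradation reactions: 5 processes x 8 complexes
  moves <- data.frame(
    class = c("internalization", "recycle4", "transfer4to11", "recycle11", "degradation"),
    proc = TRAFFIC_PROCESSES,
    from = c("SURFACE", "RAB4", "RAB4", "RAB11", "RAB4"),
    to = c("RAB4", "SURFACE", "RAB11", "SURFACE", "DEGRADED"),
    stringsAsFactors = FALSE
  )
  for (cx in COMPLEXES) {
    tr <- TRAFFIC_CLASS_OF_COMPLEX[[cx]]
    for (i in seq_len(nrow(moves))) {
      add(moves$class[i], moves$from[i], cx, cx,
          paste(moves$proc[i], tr, sep = "."), 1,
          params$trafficking[moves$proc[i], tr],
          state_index(moves$from[i], cx),
          state_index(moves$to[i], cx), 1)
    }
  }

  # 21 + 21 coupling/uncoupling reactions: 7 rules x 3 compartments.
  # Effective coupling constant = base kc / membrane area of the compartment.
  rules <- coupling_rules()
  for (comp in LIVE_COMPARTMENTS) {
    area <- params$areas[[comp]]
    for (i in seq_len(nrow(rules))) {
      pair <- rules$pair[i]
      r1 <- rules$reactant1[i]; r2 <- rules$reactant2[i]; pr <- rules$product[i]
      add("coupling", comp, c(r1, r2), pr,
          paste0("kc.", pair), rules$fw_factor[i],
          params$kc[[pair]] / area,
          c(state_index(comp, r1), state_index(comp, r2)),
          state_index(comp, pr), 1)
      add("uncoupling", comp, pr, c(r1, r2),
          paste0("kd.", pair), rules$bw_factor[i],
          params$kd[[pair]],
          state_index(comp, pr),
          state_index(comp, unique(c(r1, r2))),
          if (r1 == r2) 2 else c(1, 1))
    }
  }

  build_network(rx, params)
}

# Assemble the internal arrays: reactant index pair per reaction, rate
# constant (already including the statistical factor and area scaling), and
# sparse stoichiometry triplets for the 32 x 85 stoichiometry matrix.
build_network <- function(rx, params) {
  n <- length(rx)
  idx1 <- idx2 <- integer(n)
  kfac <- numeric(n)
  tri_i <- integer(0); tri_j <- integer(0); tri_v <- numeric(0)
  for (j in seq_len(n)) {
    r <- rx[[j]]
    ri <- r$r_idx
    idx1[j] <- if (length(ri) >= 1) ri[1] else 0L
    idx2[j] <- if (length(ri) >= 2) ri[2] else 0L
    kfac[j] <- r$k * r$factor
    # reactant consumption
    if (length(ri) > 0) {
      cons <- table(ri)
      tri_i <- c(tri_i, as.integer(names(cons)))
      tri_j <- c(tri_j, rep(j, length(cons)))
      tri_v <- c(tri_v, -as.numeric(cons))
    }
    # product formation (p_stoich handles "2 R1" style products)
    tri_i <- c(tri_i, r$p_idx)
    tri_j <- c(tri_j, rep(j, length(r$p_idx)))
    tri_v <- c(tri_v, r$p_stoich)
  }
  reactions <- data.frame(
    reaction_id = seq_len(n),
    class = vapply(rx, `[[`, "", "class"),
    compartment = vapply(rx, `[[`, "", "compartment"),
    reactants = vapply(rx, `[[`, "", "reactants"),
    products = vapply(rx, `[[`, "", "products"),
    rate_constant_name = vapply(rx, `[[`, "", "rate_constant_name"),
    factor = vapply(rx, `[[`, 0, "factor"),
    rate_constant = vapply(rx, `[[`, 0, "k"),
    stringsAsFactors = FALSE
  )
  # duplicated (i, j) triplets must accumulate, so fill by loop
  S <- matrix(0, nrow = length(SPECIES_LABELS), ncol = n,
              dimnames = list(SPECIES_LABELS, NULL))
  for (m in seq_along(tri_i)) S[tri_i[m], tri_j[m]] <- S[tri_i[m], tri_j[m]] + tri_v[m]

  # precomputed lookups for fast rate refresh: index of each reaction's rate
  # constant in the flattened parameter vector c(trafficking, k_prod, kc, kd)
  parts <- strsplit(reactions$rate_constant_name, ".", fixed = TRUE)
  base <- vapply(parts, `[[`, "", 1)
  tgt <- vapply(parts, `[[`, "", 2)
  pidx <- integer(n)
  for (j in seq_len(n)) {
    pidx[j] <- switch(base[j],
      k_prod = 15L + match(tgt[j], RECEPTORS),
      kc = 18L + match(tgt[j], COUPLING_PAIRS),
      kd = 21L + match(tgt[j], COUPLING_PAIRS),
      (match(tgt[j], RECEPTORS) - 1L) * 5L + match(base[j], TRAFFIC_PROCESSES)
    )
  }
  areadiv <- ifelse(base == "kc", match(reactions$compartment, LIVE_COMPARTMENTS), 0L)

  # precomputed Jacobian triplets: d(rate_j)/d(state_i) =
  # kfac_j * coef * state[mult] (mult = 0 means the derivative is kfac_j*coef)
  jj <- ii <- mm <- cc <- integer(0)
  for (j in seq_len(n)) {
    i1 <- idx1[j]; i2 <- idx2[j]
    if (i1 == 0L) next
    if (i2 == 0L) {
      jj <- c(jj, j); ii <- c(ii, i1); mm <- c(mm, 0L); cc <- c(cc, 1L)
    } else if (i1 == i2) {
      jj <- c(jj, j); ii <- c(ii, i1); mm <- c(mm, i1); cc <- c(cc, 2L)
    } else {
      jj <- c(jj, j, j); ii <- c(ii, i1, i2); mm <- c(mm, i2, i1); cc <- c(cc, 1L, 1L)
    }
  }

  structure(
    list(
      reactions = reactions,
      species = enumerate_species(),
      params = params,
      idx1 = idx1, idx2 = idx2, kfac = kfac,
      S = S,
      tri = list(i = tri_i, j = tri_j, v = tri_v),
      pidx = pidx, areadiv = areadiv, factor = reactions$factor,
      jac = list(j = jj, i = ii, mult = mm, coef = cc),
      # shared scratch space (reference semantics survive list copies):
      # warm starts for the production inner loop across nearby parameter
      # sets, e.g. during finite-difference sweeps of a fit
      cache = new.env(parent = emptyenv())
    ),
    class = "traffic_network"
  )
}

#' @export
print.traffic_network <- function(x, ...) {
  cat("Receptor trafficking reaction network:",
      nrow(x$S), "species,", nrow(x$reactions), "reactions\n")
  print(table(x$reactions$class))
  invisible(x)
}

# Recompute the rate-constant vector of an existing network for a new
# parameter set (same topology). Much cheaper than expand_reactions when a
# fit or scan repeatedly edits rate constants.
update_network_rates <- function(network, params) {
  pvec <- c(as.vector(params$trafficking), params$k_prod, params$kc, params$kd)
  k <- unname(pvec[network$pidx])
  div <- network$areadiv > 0L
  k[div] <- k[div] / params$areas[network$areadiv[div]]
  network$reactions$rate_constant <- k
  network$kfac <- k * network$factor
  network$params <- params
  network
}

#' Mass-action right-hand side of the model ODE system
#'
#' Computes the time derivative of the 32-entry state under the mass-action
#' rate laws of the network. Degraded pools only ever receive inflow, so the
#' receptor-weighted grand total (surface + endosomal + degraded) changes only
#' through production.
#'
#' @param state Named numeric state vector of length 32 (see
#'   [enumerate_species()]), nonnegative.
#' @param network A `traffic_network` from [expand_reactions()].
#' @return Derivative vector (per second), same length/names as `state`.
#' @export
rhs <- function(state, network) {
  drop(network$S %*% reaction_rates(state, network))
}

reaction_rates <- function(state, network) {
  v <- network$kfac
  h1 <- network$idx1 > 0L
  v[h1] <- v[h1] * state[network$idx1[h1]]
  h2 <- network$idx2 > 0L
  v[h2] <- v[h2] * state[network$idx2[h2]]
  v
}

# Analytic Jacobian of rhs() restricted to arbitrary row/col subsets, using
# the triplets precomputed in build_network: for one reactant k*x1 the
# derivative is k; for two reactants k*x1*x2 it is k*x2 / k*x1; for identical
# reactants k*x^2 it is 2*k*x.
rhs_jacobian <- function(state, network, rows = seq_along(state),
                         cols = seq_along(state)) {
  jc <- network$jac
  vals <- network$kfac[jc$j] * jc$coef
  has_mult <- jc$mult > 0L
  vals[has_mult] <- vals[has_mult] * state[jc$mult[has_mult]]
  Dr <- matrix(0, nrow = length(network$kfac), ncol = length(state))
  Dr[cbind(jc$j, jc$i)] <- vals
  network$S[rows, , drop = FALSE] %*% Dr[, cols, drop = FALSE]
}

#' Export the reaction network as a tabular reaction list
#'
#' @param network A `traffic_network`.
#' @param path CSV file path.
#' @return `path`, invisibly. Columns: `reaction_id`, `class`, `compartment`,
#'   `reactants`, `products`, `rate_constant_name`, `factor`,
#'   `rate_constant` (effective per-cell units).
#' @export
write_network_csv <- function(network, path) {
  utils::write.csv(network$reactions, path, row.names = FALSE)
  invisible(path)
}

# Flatten the network to the fixed-length parameter vector consumed by the
# compiled integrator core (see src/traffic_core.c).
network_to_cparms <- function(network) {
  tri <- network$tri
  nr <- length(network$kfac)
  m <- length(tri$i)
  p <- c(nr, m, network$kfac, network$idx1, network$idx2, tri$i, tri$j, tri$v)
  length(p) <- 2048L  # pad to the fixed buffer length of the C core
  p[is.na(p)] <- 0
  p
}
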