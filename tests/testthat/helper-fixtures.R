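# Shared fixtures for the test suite. Everything is built in code; the
# "reference" trafficking set below is an arbitrary but realistic HUVEC-like
# configuration used where tests need fixed, feasible rate constants.

ref_trafficking <- function() {
  matrix(
    c(
      1.3e-2, 2.5e-4, 2.7e-4, # k_int
      2.0e-3, 1.0e-5, 1.0e-3, # k_rec4
      2.0e-3, 3.0e-5, 1.5e-3, # k_4to11
      1.0e-3, 1.0e-4, 8.0e-4, # k_rec11
      8.0e-4, 2.9e-4, 2.0e-6  # k_deg
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(c("k_int", "k_rec4", "k_4to11", "k_rec11", "k_deg"),
                    c("R1", "R2", "N1"))
  )
}

ref_params <- function(coupling = TRUE, k_prod = c(R1 = 0, R2 = 0, N1 = 0)) {
  kc <- if (coupling) c(R1R1 = 1e-4, R2R2 = 1e-4, R1N1 = 8e-4) else
    c(R1R1 = 0, R2R2 = 0, R1N1 = 0)
  traffic_params(ref_trafficking(), k_prod = k_prod, kc = kc)
}

# A single-receptor configuration (only R1 produced, coupling off) whose
# live dynamics are exactly the 3-compartment linear system used by the
# matrix-exponential oracles.
single_receptor_params <- function(k_int = 1e-3, k_rec4 = 5e-4,
                                   k_4to11 = 3e-4, k_rec11 = 2e-4,
                                   k_deg = 4e-4, k_prod = 1) {
  tr <- matrix(1e-3, 5, 3)
  tr[, 1] <- c(k_int, k_rec4, k_4to11, k_rec11, k_deg)
  traffic_params(tr, k_prod = c(R1 = k_prod, R2 = 0, N1 = 0),
                 kc = c(R1R1 = 0, R2R2 = 0, R1N1 = 0))
}

# Independent linear oracle: the 4x4 transition matrix (surface, Rab4,
# Rab11, degraded) of one receptor's trafficking, assembled directly from
# the compartment diagram, never from the package's network expansion.
single_receptor_matrix <- function(k_int, k_rec4, k_4to11, k_rec11, k_deg) {
  matrix(c(
    -k_int,            k_rec4,                      k_rec11, 0,
     k_int,          -(k_rec4 + k_4to11 + k_deg),   0,       0,
     0,                k_4to11,                    -k_rec11, 0,
     0,                k_deg,                       0,       0
  ), nrow = 4, byrow = TRUE)
}

# Receptor-weighted grand totals (live + degraded) per receptor for every
# row of a trajectory's state matrix.
grand_totals <- function(state_matrix) {
  W <- vegfrtraffic:::COMPLEX_COMPOSITION
  all_W <- W[, rep(colnames(W), 4)]
  t(all_W %*% t(state_matrix))
}
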