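# Protocol simulation, steady states, aggregation, normalization

test_that("steady state is a fixed point: unperturbed aggregates constant over 24 h", {
  p <- ref_params()
  p <- solve_production_rates(p, c(R1 = 1800, R2 = 4900, N1 = 68000))
  ss <- steady_state(p)
  traj <- simulate_protocol(p, ss, times = seq(0, 24 * 3600, length.out = 25))
  tot <- trajectory_totals(traj)
  surf <- vegfrtraffic:::trajectory_surface(traj)
  expect_lt(max(abs(tot / rep(tot[1, ], each = nrow(tot)) - 1)), 1e-3)
  expect_lt(max(abs(surf / rep(surf[1, ], each = nrow(surf)) - 1)), 1e-3)
})

test_that("with production off, receptor totals including degraded are conserved", {
  p <- ref_params(k_prod = c(R1 = 2, R2 = 1, N1 = 4))
  ss <- steady_state(p)
  p0 <- p
  p0$k_prod[] <- 0
  traj <- simulate_protocol(p0, ss, times = seq(0, 24 * 3600, length.out = 13))
  g <- grand_totals(traj$state)
  drift <- abs(g / rep(g[1, ], each = nrow(g)) - 1)
  expect_lt(max(drift), 1e-6)
})

test_that("trajectories from nonnegative states stay nonnegative", {
  p <- ref_params(k_prod = c(R1 = 0.5, R2 = 0.1, N1 = 2))
  set.seed(5)
  x0 <- empty_state()
  x0[] <- runif(32, 0, 1e4)
  traj <- simulate_protocol(p, x0, times = seq(0, 12 * 3600, length.out = 25))
  expect_gt(min(traj$state), -1e-6)
})

test_that("uncoupled single-receptor trajectory matches the matrix exponential", {
  ks <- c(2e-3, 7e-4, 4e-4, 9e-5, 6e-4)
  p <- single_receptor_params(ks[1], ks[2], ks[3], ks[4], ks[5], k_prod = 0)
  A <- single_receptor_matrix(ks[1], ks[2], ks[3], ks[4], ks[5])
  idx <- c("SURFACE.R1", "RAB4.R1", "RAB11.R1", "DEGRADED.R1")
  x0 <- empty_state()
  x0[idx] <- c(4000, 1500, 800, 0)
  times <- c(0, 600, 3600, 4 * 3600, 24 * 3600)
  traj <- simulate_protocol(p, x0, times = times, rtol = 1e-10, atol = 1e-8)
  for (i in seq_along(times)) {
    oracle <- as.numeric(Matrix::expm(A * times[i]) %*% x0[idx])
    got <- traj$state[i, idx]
    expect_equal(unname(got), oracle, tolerance = 1e-6)
  }
})

test_that("CHX from steady state gives monotone non-increasing whole-cell totals", {
  p <- ref_params()
  p <- solve_production_rates(p)
  ss <- steady_state(p)
  traj <- simulate_protocol(p, ss, times = seq(0, 24 * 3600, length.out = 49),
                            perturbation_spec = perturbation("CHX"))
  tot <- trajectory_totals(traj)
  for (r in colnames(tot)) {
    expect_true(all(diff(tot[, r]) <= 1e-6 * tot[1, r]),
                label = paste("monotone decay of", r))
  }
})

test_that("single-receptor CHX total matches the matrix-exponential oracle", {
  ks <- c(1.5e-3, 6e-4, 2e-4, 1e-4, 5e-4)
  p <- single_receptor_params(ks[1], ks[2], ks[3], ks[4], ks[5], k_prod = 0.9)
  ss <- steady_state(p)
  A <- single_receptor_matrix(ks[1], ks[2], ks[3], ks[4], ks[5])
  idx <- c("SURFACE.R1", "RAB4.R1", "RAB11.R1", "DEGRADED.R1")
  times <- c(0, 1800, 3600, 2 * 3600, 8 * 3600)
  traj <- simulate_protocol(p, ss, times = times,
                            perturbation_spec = perturbation("CHX"),
                            rtol = 1e-10, atol = 1e-8)
  tot <- trajectory_totals(traj)[, "R1"]
  for (i in seq_along(times)) {
    oracle <- as.numeric(Matrix::expm(A * times[i]) %*% ss[idx])
    expect_equal(unname(tot[i]), sum(oracle[1:3]), tolerance = 1e-6)
  }
})

test_that("steady-state errors are reported for unbounded configurations", {
  # production with no degradation route grows without bound
  tr <- ref_trafficking()
  tr["k_deg", ] <- 0
  p <- traffic_params(tr, k_prod = c(R1 = 1, R2 = 1, N1 = 1),
                      kc = c(R1R1 = 0, R2R2 = 0, R1N1 = 0))
  expect_error(steady_state(p), "steady state")
  # the empty system has the zero steady state
  p0 <- ref_params(k_prod = c(R1 = 0, R2 = 0, N1 = 0))
  expect_equal(as.numeric(steady_state(p0)), rep(0, 32))
})

test_that("flux balance holds per compartment and receptor at steady state", {
  p <- solve_production_rates(ref_params())
  ss <- steady_state(p)
  fx <- compute_fluxes(p, ss)
  net <- attr(fx, "net")
  prod_flux <- sum(p$k_prod)
  expect_lt(max(abs(net)) / prod_flux, 1e-6)
})

test_that("siRNA perturbations edit only the targeted rate constants", {
  p <- ref_params(k_prod = c(R1 = 1, R2 = 1, N1 = 1))
  edited <- vegfrtraffic:::perturb_params(p, perturbation("SIRNA_RAB4"))
  expect_equal(edited$trafficking["k_rec4", ], 0.2 * p$trafficking["k_rec4", ])
  same <- setdiff(rownames(p$trafficking), "k_rec4")
  expect_identical(edited$trafficking[same, ], p$trafficking[same, ])
  expect_identical(edited$k_prod, p$k_prod)
  expect_identical(edited$kc, p$kc)
  # double knockdown hits both recycling arms; transfer stays untouched by
  # default and scales only when requested
  dbl <- vegfrtraffic:::perturb_params(p, perturbation("SIRNA_DOUBLE"))
  expect_equal(dbl$trafficking["k_rec11", ], 0.2 * p$trafficking["k_rec11", ])
  expect_identical(dbl$trafficking["k_4to11", ], p$trafficking["k_4to11", ])
  dbl2 <- vegfrtraffic:::perturb_params(
    p, perturbation("SIRNA_DOUBLE", rab4_scales_transfer = TRUE))
  expect_equal(dbl2$trafficking["k_4to11", ], 0.2 * p$trafficking["k_4to11", ])
  # CHX zeroes production and nothing else
  chx <- vegfrtraffic:::perturb_params(p, perturbation("CHX"))
  expect_equal(unname(chx$k_prod), rep(0, 3))
  expect_identical(chx$trafficking, p$trafficking)
  # CHQ scales degradation by 1 - f
  chq <- vegfrtraffic:::perturb_params(p, perturbation("CHQ", chq_fraction = 0.42))
  expect_equal(chq$trafficking["k_deg", ], 0.58 * p$trafficking["k_deg", ])
})

test_that("aggregation weights complexes by receptor stoichiometry", {
  x <- empty_state()
  x[["SURFACE.R1R1N1N1"]] <- 5
  agg <- aggregate_state(x)
  expect_equal(agg$surface[agg$receptor == "R1"], 10)
  expect_equal(agg$surface[agg$receptor == "N1"], 10)
  expect_equal(agg$surface[agg$receptor == "R2"], 0)
  # internal = rab4 + rab11; degraded never contributes to total
  x[["RAB4.R1"]] <- 3; x[["RAB11.R1N1"]] <- 2; x[["DEGRADED.R1"]] <- 1e6
  agg <- aggregate_state(x)
  r1 <- agg[agg$receptor == "R1", ]
  expect_equal(r1$internal, r1$rab4 + r1$rab11)
  expect_equal(r1$total, r1$surface + r1$internal)
  expect_equal(r1$internal, 5)
  expect_equal(r1$degraded, 1e6)
  # 1,800 surface / 18,000 internal -> 9.1% on the surface
  y <- empty_state()
  y[["SURFACE.R1"]] <- 1800
  y[["RAB4.R1"]] <- 18000
  expect_equal(aggregate_state(y)$pct_surface[1], 100 * 1800 / 19800,
               tolerance = 1e-12)
})

test_that("normalization maps control to 1 and is linear", {
  x <- c(10, 5, 2.5)
  expect_equal(normalize_to_control(x), c(1, 0.5, 0.25))
  expect_equal(normalize_to_control(2 * x, control = x[1]), 2 * c(1, 0.5, 0.25))
  m <- cbind(a = c(4, 2), b = c(10, 20))
  fc <- normalize_to_control(m)
  expect_equal(fc[1, ], c(a = 1, b = 1))
  expect_equal(fc[2, ], c(a = 0.5, b = 2))
  expect_error(normalize_to_control(c(0, 1)), "control")
})

test_that("trajectory tables are tidy and carry fold changes", {
  p <- solve_production_rates(ref_params())
  ss <- steady_state(p)
  traj <- simulate_protocol(p, ss, times = c(0, 3600, 7200))
  tab <- trajectory_to_table(traj)
  expect_setequal(names(tab),
                  c("time_s", "receptor", "compartment", "count", "fold_change"))
  expect_equal(nrow(tab), 3 * 3 * 4)
  expect_equal(tab$fold_change[tab$time_s == 0], rep(1, 12))
})

test_that("parameter sets round-trip through YAML", {
  p <- solve_production_rates(ref_params())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params_yaml(p, path)
  q <- read_params_yaml(path)
  expect_equal(q$trafficking, p$trafficking)
  expect_equal(q$k_prod, p$k_prod)
  expect_equal(q$kc, p$kc)
  expect_equal(q$areas, p$areas)
})
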