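# Calibration dataset, production solve, cost, multistart machinery

test_that("the HUVEC dataset has 24 rows, 8 per receptor, with the measured values", {
  ds <- huvec_dataset()
  expect_equal(nrow(ds), 24L)
  expect_equal(unname(table(ds$receptor)), rep(8L, 3), ignore_attr = TRUE)
  per_rec <- table(ds$receptor, ds$type)
  expect_true(all(per_rec[, "surface_count"] == 1))
  expect_true(all(per_rec[, "surface_percent"] == 1))
  expect_true(all(per_rec[, "sirna_double_foldchange"] == 1))
  expect_true(all(per_rec[, "chx_foldchange"] == 5))
  # measured anchors
  sc <- ds[ds$type == "surface_count", ]
  expect_equal(sc$value[match(c("R1", "R2", "N1"), sc$receptor)],
               c(1800, 4900, 68000))
  sp <- ds[ds$type == "surface_percent", ]
  expect_equal(sp$value[match(c("R1", "R2", "N1"), sp$receptor)],
               c(10, 51, 74))
  expect_equal(ds$value[ds$type == "sirna_double_foldchange"], rep(1, 3))
  # CHX targets: half-life 45 min for VEGFR1 -> fold 0.5 at 45 min; flat NRP1
  ds45 <- huvec_dataset(chx_hours = 0.75)
  expect_equal(ds45$value[ds45$type == "chx_foldchange" & ds45$receptor == "R1"],
               0.5)
  expect_equal(ds$value[ds$type == "chx_foldchange" & ds$receptor == "N1"],
               rep(1, 5))
  # VEGFR2 decays with the 82.5 min midpoint half-life
  r2 <- ds[ds$type == "chx_foldchange" & ds$receptor == "R2", ]
  expect_equal(r2$value, 2^(-r2$time_h * 60 / 82.5))
})

test_that("datasets round-trip through the shared CSV schema", {
  ds <- huvec_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_s3_class(back, "calibration_dataset")
  bad <- data.frame(x = 1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_dataset_csv(path2), "columns")
})

test_that("production solve hits surface targets and is deterministic", {
  p <- ref_params()
  solved <- solve_production_rates(p, c(R1 = 1800, R2 = 4900, N1 = 68000))
  ss <- steady_state(solved)
  agg <- aggregate_state(ss)
  expect_equal(agg$surface, c(1800, 4900, 68000), tolerance = 1e-6)
  solved2 <- solve_production_rates(p, c(R1 = 1800, R2 = 4900, N1 = 68000))
  expect_identical(solved$k_prod, solved2$k_prod)
  # zero targets give zero production
  z <- solve_production_rates(p, c(R1 = 0, R2 = 0, N1 = 0))
  expect_equal(unname(z$k_prod), rep(0, 3))
})

test_that("uncoupled production solve matches the closed-form linear formula", {
  ks <- c(k_int = 3e-3, k_rec4 = 8e-4, k_4to11 = 5e-4, k_rec11 = 2e-4,
          k_deg = 7e-4)
  p <- single_receptor_params(ks[1], ks[2], ks[3], ks[4], ks[5])
  s_target <- 2500
  solved <- solve_production_rates(p, c(R1 = s_target, R2 = 0, N1 = 0))
  # symbolic steady state of the 3-compartment linear system:
  # k_prod = S k_int k_deg / (k_deg + k_rec4 + k_4to11)
  oracle <- s_target * ks["k_int"] * ks["k_deg"] /
    (ks["k_deg"] + ks["k_rec4"] + ks["k_4to11"])
  expect_equal(solved$k_prod[["R1"]], unname(oracle), tolerance = 1e-8)
})

test_that("infeasible production targets are rejected", {
  tr <- ref_trafficking()
  tr["k_int", "R2"] <- 0
  p <- traffic_params(tr, kc = c(R1R1 = 0, R2R2 = 0, R1N1 = 0))
  expect_error(solve_production_rates(p, c(R1 = 100, R2 = 100, N1 = 100)),
               "infeasible")
})

test_that("solved NRP1 production increases with the VEGFR1-NRP1 coupling rate", {
  kp_of <- function(kc_rn) {
    p <- traffic_params(ref_trafficking(),
                        kc = c(R1R1 = 1e-4, R2R2 = 1e-4, R1N1 = kc_rn))
    solve_production_rates(p)$k_prod[["N1"]]
  }
  kps <- vapply(c(0, 2e-4, 8e-4, 3.2e-3), kp_of, 0)
  expect_true(all(diff(kps) > 0))
})

test_that("cost is zero at the generating parameters of a noiseless synthetic dataset", {
  truth <- solve_production_rates(ref_params())
  ds <- generate_measurements(truth, cv = 0)
  expect_lt(traffic_cost(truth, ds), 1e-6)
  # and invariant to row order
  perm <- sample(nrow(ds))
  ds_perm <- ds[perm, ]
  p_other <- ref_params()
  p_other$trafficking["k_deg", "R1"] <- 2e-3
  expect_equal(traffic_cost(p_other, ds_perm), traffic_cost(p_other, ds),
               tolerance = 1e-10)
})

test_that("a single start at the truth of a noiseless dataset stays at the optimum", {
  truth <- solve_production_rates(ref_params())
  ds <- generate_measurements(truth, cv = 0)
  sv <- matrix(as.vector(truth$trafficking), nrow = 1)
  ens <- multistart_fit(ds, n_starts = 1, start_values = sv, seed = 1)
  f <- ens$fits[[1]]
  expect_true(f$converged)
  expect_lt(f$cost, 1e-6)
  expect_equal(as.vector(f$trafficking), as.vector(truth$trafficking),
               tolerance = 0.05)
})

test_that("multistart fits are seed-reproducible and respect the bounds", {
  ds <- huvec_dataset()
  ens1 <- multistart_fit(ds, n_starts = 2, seed = 11)
  ens2 <- multistart_fit(ds, n_starts = 2, seed = 11)
  for (i in 1:2) {
    expect_identical(ens1$fits[[i]]$initial, ens2$fits[[i]]$initial)
    expect_identical(ens1$fits[[i]]$trafficking, ens2$fits[[i]]$trafficking)
    expect_identical(ens1$fits[[i]]$cost, ens2$fits[[i]]$cost)
    tr <- ens1$fits[[i]]$trafficking
    expect_true(all(tr >= 1e-6 - 1e-12) && all(tr <= 1e-1 + 1e-12))
    expect_true(all(ens1$fits[[i]]$initial >= 1e-6) &&
                all(ens1$fits[[i]]$initial <= 1e-1))
  }
})

test_that("consensus production re-solve reproduces the calibration surface targets", {
  ds <- huvec_dataset()
  truth <- solve_production_rates(ref_params())
  sv <- matrix(rep(as.vector(truth$trafficking), 3), nrow = 3, byrow = TRUE)
  ens <- multistart_fit(generate_measurements(truth, cv = 0), n_starts = 3,
                        start_values = sv, seed = 2)
  cons <- summarize_fits(ens)
  ss <- steady_state(cons$params)
  agg <- aggregate_state(ss)
  expect_equal(agg$surface, c(1800, 4900, 68000), tolerance = 1e-4)
  # an ensemble of identical starts summarizes to (numerically) that
  # parameter set; warm-started inner solves may differ in the last digits
  expect_equal(as.vector(cons$params$trafficking),
               as.vector(ens$fits[[1]]$trafficking), tolerance = 1e-3)
  # percentile spread is reported per parameter
  expect_true(all(c("q05", "q95", "median", "geomean") %in% names(cons$summary)))
  expect_true(all(cons$summary$q05 <= cons$summary$q95))
})

test_that("initial-final correlation is 1 for identity fits and NA for constant ones", {
  ds <- huvec_dataset()
  # fabricate a minimal ensemble by hand: optimized == initial
  set.seed(9)
  fits <- lapply(1:5, function(i) {
    v <- 10^runif(15, -6, -1)
    names(v) <- vegfrtraffic:::SENSITIVITY_PARAMS()[1:15]
    list(initial = v, trafficking = vegfrtraffic:::trafficking_from_vector(v),
         k_prod = c(R1 = 1, R2 = 1, N1 = 1), cost = 0, converged = TRUE)
  })
  ens <- structure(list(fits = fits, dataset = ds,
                        params_template = ref_params()),
                   class = "fit_ensemble")
  corr <- initial_final_correlation(ens)
  expect_equal(corr$correlation, rep(1, 15), tolerance = 1e-12)
  expect_false(any(corr$degenerate))
  # constant optimized values: undefined, flagged
  const <- vegfrtraffic:::trafficking_from_vector(
    stats::setNames(rep(1e-3, 15), vegfrtraffic:::SENSITIVITY_PARAMS()[1:15]))
  fits2 <- lapply(fits, function(f) { f$trafficking <- const; f })
  ens2 <- structure(list(fits = fits2, dataset = ds,
                         params_template = ref_params()),
                    class = "fit_ensemble")
  corr2 <- initial_final_correlation(ens2)
  expect_true(all(is.na(corr2$correlation)))
  expect_true(all(corr2$degenerate))
  expect_error(initial_final_correlation(
    structure(list(fits = fits[1:2]), class = "fit_ensemble")), "3")
})
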