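# Structure of the state space and rule-expanded reaction network

test_that("state space has 32 entries: 8 complexes x 3 live compartments + 8 degraded pools", {
  sp <- enumerate_species()
  expect_equal(nrow(sp), 32L)
  live <- sp[sp$compartment != "DEGRADED", ]
  expect_equal(unname(table(live$compartment)[c("SURFACE", "RAB4", "RAB11")]),
               rep(8L, 3), ignore_attr = TRUE)
  expect_equal(sum(sp$compartment == "DEGRADED"), 8L)
  # VEGFR2 never co-occurs with VEGFR1 or NRP1; N1 copies never exceed R1
  comp <- vegfrtraffic:::COMPLEX_COMPOSITION
  with_r2 <- comp["R2", ] > 0
  expect_true(all(comp[c("R1", "N1"), with_r2] == 0))
  dimers <- comp[, comp["R1", ] > 0, drop = FALSE]
  expect_true(all(dimers["N1", ] <= dimers["R1", ]))
})

test_that("monomer-only enumeration (coupling rules removed) has 12 entries", {
  sp <- enumerate_species(include_complexes = FALSE)
  expect_equal(nrow(sp), 12L)
  expect_setequal(unique(sp$complex), c("R1", "R2", "N1"))
})

test_that("rule expansion yields 85 reactions partitioned 3/40/21/21", {
  net <- expand_reactions(ref_params())
  expect_equal(nrow(net$reactions), 85L)
  counts <- table(net$reactions$class)
  expect_equal(unname(counts[["production"]]), 3L)
  traffic <- sum(counts[c("internalization", "recycle4", "transfer4to11",
                          "recycle11", "degradation")])
  expect_equal(unname(traffic), 40L)
  expect_equal(unname(counts[["coupling"]]), 21L)
  expect_equal(unname(counts[["uncoupling"]]), 21L)
  # 7 coupling rules instantiated once per live compartment
  cpl <- net$reactions[net$reactions$class == "coupling", ]
  expect_equal(unname(table(cpl$compartment)), rep(7L, 3), ignore_attr = TRUE)
})

test_that("complexes inherit trafficking constants from their receptor content", {
  p <- ref_params()
  net <- expand_reactions(p)
  rx <- net$reactions
  # every VEGFR1-containing complex (incl. VEGFR1-NRP1 species) uses VEGFR1
  # constants; the NRP1 monomer uses NRP1's
  for (cx in c("R1R1", "R1N1", "R1R1N1", "R1R1N1N1")) {
    row <- rx[rx$class == "internalization" & rx$reactants == cx, ]
    expect_equal(row$rate_constant_name, "k_int.R1")
    expect_equal(row$rate_constant, p$trafficking["k_int", "R1"])
  }
  expect_equal(rx[rx$class == "degradation" & rx$reactants == "N1",
                  "rate_constant_name"], "k_deg.N1")
  expect_equal(rx[rx$class == "degradation" & rx$reactants == "R2R2",
                  "rate_constant_name"], "k_deg.R2")
})

test_that("coupling constants are scaled by the source compartment's membrane area", {
  p <- traffic_params(ref_trafficking(),
                      kc = c(R1R1 = 1e-4, R2R2 = 1e-4, R1N1 = 8e-4),
                      areas = c(SURFACE = 1000, RAB4 = 100, RAB11 = 100))
  net <- expand_reactions(p)
  rx <- net$reactions
  surf <- rx[rx$class == "coupling" & rx$compartment == "SURFACE" &
             rx$rate_constant_name == "kc.R1R1", ]
  # base 1e-4 (molec/um^2)^-1 s^-1 over 1000 um^2 -> 1e-7 (molec/cell)^-1
  # s^-1, shared by all three rules that form a VEGFR1-VEGFR1 bond
  expect_equal(surf$rate_constant, rep(1e-7, nrow(surf)))
  expect_gt(nrow(surf), 0)
  rab4 <- rx[rx$class == "coupling" & rx$compartment == "RAB4" &
             rx$rate_constant_name == "kc.R1R1", ]
  expect_equal(rab4$rate_constant, rep(1e-6, nrow(rab4)))
  # area of one leaves the base constant unchanged
  p1 <- traffic_params(ref_trafficking(), kc = c(R1R1 = 1e-4, R2R2 = 0, R1N1 = 0),
                       areas = c(SURFACE = 1, RAB4 = 1, RAB11 = 1))
  net1 <- expand_reactions(p1)
  s1 <- net1$reactions[net1$reactions$class == "coupling" &
                       net1$reactions$rate_constant_name == "kc.R1R1", ]
  expect_equal(s1$rate_constant, rep(1e-4, nrow(s1)))
  # uncoupling is first order and never area-scaled
  und <- rx[rx$class == "uncoupling" & rx$rate_constant_name == "kd.R1R1", ]
  expect_equal(unique(und$rate_constant), p$kd[["R1R1"]])
})

test_that("NRP1 binding to the VEGFR1 dimer carries statistical factor 2", {
  net <- expand_reactions(ref_params())
  rx <- net$reactions
  dimer_bind <- rx[rx$class == "coupling" & rx$reactants == "R1R1 + N1", ]
  expect_equal(dimer_bind$factor, rep(2, 3))
  mono_bind <- rx[rx$class == "coupling" & rx$reactants == "R1 + N1", ]
  expect_equal(mono_bind$factor, rep(1, 3))
  # two dissociable NRP1 on the doubly occupied complex
  double_un <- rx[rx$class == "uncoupling" & rx$products == "R1R1N1 + N1", ]
  expect_equal(double_un$factor, rep(2, 3))
})

test_that("nonpositive membrane areas are rejected", {
  expect_error(traffic_params(ref_trafficking(),
                              areas = c(SURFACE = 0, RAB4 = 100, RAB11 = 100)),
               "areas")
  expect_error(traffic_params(ref_trafficking(),
                              areas = c(SURFACE = 1000, RAB4 = -5, RAB11 = 100)),
               "areas")
})

test_that("rhs of the all-zero state is production into surface monomers only", {
  p <- ref_params(k_prod = c(R1 = 1.5, R2 = 2.5, N1 = 0.5))
  net <- expand_reactions(p)
  d <- rhs(empty_state(), net)
  expect_equal(d[["SURFACE.R1"]], 1.5)
  expect_equal(d[["SURFACE.R2"]], 2.5)
  expect_equal(d[["SURFACE.N1"]], 0.5)
  d[c("SURFACE.R1", "SURFACE.R2", "SURFACE.N1")] <- 0
  expect_equal(unname(d), rep(0, 32))
})

test_that("receptor-weighted grand totals change only through production", {
  p <- ref_params(k_prod = c(R1 = 2, R2 = 0.7, N1 = 3.1))
  net <- expand_reactions(p)
  W <- vegfrtraffic:::COMPLEX_COMPOSITION
  set.seed(42)
  for (i in 1:20) {
    x <- empty_state()
    x[] <- runif(32, 0, 1e4)
    d <- rhs(x, net)
    dm <- matrix(d, nrow = 8)
    total_rate <- W %*% rowSums(dm)  # d/dt of live + degraded totals
    expect_equal(drop(total_rate), unname(p$k_prod), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("degraded pools have inflow only", {
  p <- ref_params(k_prod = c(R1 = 1, R2 = 1, N1 = 1))
  net <- expand_reactions(p)
  expect_true(all(net$S[grep("^DEGRADED", rownames(net$S)), ] >= 0))
  set.seed(7)
  x <- empty_state()
  x[] <- runif(32, 0, 1e4)
  expect_true(all(rhs(x, net)[grep("^DEGRADED", names(x))] >= 0))
})

test_that("single-receptor rhs matches the independently assembled linear system", {
  ks <- c(k_int = 2e-3, k_rec4 = 7e-4, k_4to11 = 4e-4, k_rec11 = 9e-5,
          k_deg = 6e-4)
  p <- single_receptor_params(ks[1], ks[2], ks[3], ks[4], ks[5], k_prod = 0.8)
  net <- expand_reactions(p)
  A <- single_receptor_matrix(ks[1], ks[2], ks[3], ks[4], ks[5])
  idx <- c("SURFACE.R1", "RAB4.R1", "RAB11.R1", "DEGRADED.R1")
  set.seed(11)
  for (i in 1:10) {
    x <- empty_state()
    x[idx] <- runif(4, 0, 5e3)
    d <- rhs(x, net)
    oracle <- drop(A %*% x[idx]) + c(0.8, 0, 0, 0)
    expect_equal(unname(d[idx]), oracle, tolerance = 1e-12)
    d[idx] <- 0
    expect_equal(unname(d), rep(0, 32))
  }
})

test_that("the rate-law Jacobian matches finite differences", {
  p <- ref_params(k_prod = c(R1 = 1, R2 = 2, N1 = 3))
  net <- expand_reactions(p)
  set.seed(3)
  x <- empty_state()
  x[] <- runif(32, 0, 1e4)
  J <- vegfrtraffic:::rhs_jacobian(x, net)
  h <- 1e-3
  for (j in sample(32, 8)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    fd <- (rhs(xp, net) - rhs(xm, net)) / (2 * h)
    expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-6)
  }
})

test_that("network round-trips through its CSV export", {
  net <- expand_reactions(ref_params(k_prod = c(R1 = 1, R2 = 1, N1 = 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 85L)
  expect_equal(back$rate_constant, net$reactions$rate_constant)
  expect_equal(back$class, net$reactions$class)
})

test_that("rate refresh after a parameter edit matches a fresh expansion", {
  p1 <- ref_params(k_prod = c(R1 = 1, R2 = 2, N1 = 3))
  net <- expand_reactions(p1)
  p2 <- p1
  p2$trafficking["k_deg", "R1"] <- 5e-3
  p2$kc[["R1N1"]] <- 2e-4
  p2$k_prod[["N1"]] <- 9
  upd <- vegfrtraffic:::update_network_rates(net, p2)
  fresh <- expand_reactions(p2)
  expect_equal(upd$kfac, fresh$kfac)
  expect_equal(upd$reactions$rate_constant, fresh$reactions$rate_constant)
})
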