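test_that("omega is the ternary-over-binaries ratio", {
  expect_equal(omega(6, 2, 3), 1)
  expect_equal(omega(600, 2, 3), 100)
  expect_identical(classify_cooperativity(c(100, 1, 0.2)),
                   c("positive", "none", "negative"))
  expect_error(omega(-1, 2, 3), "positive")
  expect_error(omega(1, 0, 3), "positive")
})

test_that("cooperativity summary reads a full constant set", {
  ks <- equilibrium_constants(2, 3, 0.1, 0.1,
                              K_00_12 = 600, K_00_22 = 9)
  co <- cooperativity(ks)
  expect_equal(co$omega_12, 100)
  expect_equal(co$omega_22, 1)
  expect_equal(co$classification, "positive")
})

test_that("K_DoD is identical along every formation pathway", {
  net <- default_network()
  # non-cooperative set: K_DoD is the plain product of the binaries
  cc <- close_cycles(net, equilibrium_constants(2, 3, 0.1, 0.1,
                                                K_00_12 = 6, K_00_22 = 9))
  kd <- k_dod(cc)
  expect_equal(kd$K_DoD, 6, tolerance = 1e-14)
  expect_equal(nrow(kd$pathways), 4L)
  expect_true(all(abs(kd$pathways$product - 6) < 1e-12))
  # linearity in the overall ternary constant
  cc10 <- close_cycles(net, equilibrium_constants(2, 3, 0.1, 0.1,
                                                  K_00_12 = 60,
                                                  K_00_22 = 9))
  expect_equal(k_dod(cc10)$K_DoD, 10 * kd$K_DoD, tolerance = 1e-12)
})

test_that("pathway audit passes for random cycle-closed sets", {
  set.seed(505)
  net <- default_network()
  for (i in 1:1000) {
    cc <- close_cycles(net, random_constants())
    kd <- k_dod(cc)
    spread <- diff(range(kd$pathways$product)) / max(kd$pathways$product)
    expect_lt(spread, 1e-12)
    # explicit enumeration of monomer-first vs dimer-first products
    mono_first <- oracle_path_product(cc, c("X_0 + X_1 -> X_10",
                                            "X_10 + X_2 -> X_12"))
    dimer_first <- oracle_path_product(cc, c("X_1 + X_2 -> X_D1",
                                             "X_0 + X_D1 -> X_012",
                                             "X_012 -> X_12"))
    expect_equal(mono_first, dimer_first, tolerance = 1e-12)
    expect_equal(kd$K_DoD, mono_first, tolerance = 1e-12)
  }
})

test_that("ddG is analytic, antisymmetric and additive", {
  expect_equal(ddG(1, 1)$ddG, 0)
  expect_equal(ddG(0.1, 1, RT = 0.593)$ddG, 0.593 * log(10),
               tolerance = 1e-12)
  set.seed(606)
  for (i in 1:20) {
    ka <- 10 ^ runif(1, -3, 3); kb <- 10 ^ runif(1, -3, 3)
    kc <- 10 ^ runif(1, -3, 3)
    expect_equal(ddG(ka, kb)$ddG, -ddG(kb, ka)$ddG, tolerance = 1e-12)
    expect_equal(ddG(ka, kc)$ddG, ddG(ka, kb)$ddG + ddG(kb, kc)$ddG,
                 tolerance = 1e-12)
  }
  expect_error(ddG(-1, 1), "positive")
})

test_that("sigma proxy is the affinity ratio with orientation recorded", {
  expect_equal(sigma_proxy(0.3, 0.3, "P")$sigma, 1)
  s <- sigma_proxy(0.9, 0.3, "P")
  expect_equal(s$sigma, 3)
  expect_equal(s$denominator, "R")   # printed convention: partner monomer
  expect_equal(sigma_proxy(0.9, 0.3, "P",
                           partner_of_tethered = FALSE)$denominator, "P")
  expect_error(sigma_proxy(1, 0), "positive")
})

test_that("sigma ranks sequences concordantly with planted omega", {
  net <- default_network()
  omegas <- c(2, 5, 10, 25, 60, 150, 400)
  set.seed(707)
  sigmas <- vapply(omegas, function(w) {
    truth_het <- ground_truth(
      constants = setNames(list(default_constants(omega_12 = w)), "s"),
      design = design_relative_affinity(), noise_cv = 0.01,
      noise_floor = 0, seed = sample.int(1e6, 1))
    het <- simulate_binding_dataset(truth_het, net, readout = "P")
    slope_het <- relative_affinity(het)
    # monomeric RXRalpha affinity: no PPARgamma in the assay
    truth_r <- ground_truth(
      constants = setNames(list(default_constants(omega_12 = w)), "s"),
      design = design_relative_affinity(p_nM = 0), noise_cv = 0.01,
      noise_floor = 0, seed = sample.int(1e6, 1))
    mono <- simulate_binding_dataset(truth_r, net, readout = "R")
    sigma_proxy(slope_het, relative_affinity(mono), "P")$sigma
  }, numeric(1))
  expect_gt(cor(sigmas, omegas, method = "spearman"), 0.8)
})

test_that("fitted cooperativity round-trips a planted omega", {
  net <- default_network()
  w <- 25
  truth <- default_constants(omega_12 = w, omega_22 = 10)
  ds <- simulate_binding_dataset(
    ground_truth(constants = setNames(list(truth), "s"), noise_cv = 0,
                 noise_floor = 0), net)
  f <- fit_heterodimer(ds, equilibrium_constants(0.002, 0.075, 0.05, 0.05),
                       network = net)
  w_hat <- omega(f$parameters[["K_00_12"]], 0.002, 0.075)
  expect_equal(w_hat, w, tolerance = 1e-3)
})

test_that("cooperativity map lays out per-variant results", {
  fits <- list(
    PPRE_ref = default_constants(omega_12 = 100),
    "PPRE_p3A>C" = default_constants(omega_12 = 40),
    "PPRE_p3A>G" = default_constants(omega_12 = 80))
  map <- cooperativity_map(fits, "PPRE_ref")
  expect_identical(nrow(map), 3L)
  expect_equal(map$position[map$sequence_id == "PPRE_p3A>C"], 3L)
  expect_equal(map$substituted_base[map$sequence_id == "PPRE_p3A>G"], "G")
  expect_equal(map$ddG[map$sequence_id == "PPRE_ref"], 0)
  expect_true(all(map$omega_12 > 1))   # positive cooperativity throughout
  # weaker ternary constant means positive ddG versus the reference
  expect_gt(map$ddG[map$sequence_id == "PPRE_p3A>C"], 0)
})
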