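make_closed <- function(...) close_cycles(default_network(),
                                          equilibrium_constants(...))

test_that("empty system solves to all-zero concentrations", {
  cc <- make_closed(0.1, 0.2, 0.05, 0.02, K_00_12 = 2, K_00_22 = 0.008)
  st <- solve_equilibrium(default_network(), cc, totals_vector(0, 0, 0))
  expect_true(all(st$concentration == 0))
  ks <- simulate_kinetics(default_network(), cc, totals_vector(0, 0, 0))
  expect_true(all(ks$concentration == 0))
})

test_that("one-site subsystem matches the closed-form quadratic", {
  # only P and DNA present: the network reduces to P + D <-> PD
  cc <- make_closed(0.1, 0.2, 0.05, 0.02, K_00_12 = 2, K_00_22 = 0.008)
  st <- solve_equilibrium(default_network(), cc, totals_vector(10, 10, 0))
  expect_equal(st["X_10", "concentration"],
               oracle_quadratic_bound(0.1, 10, 10), tolerance = 1e-9)
  ks <- simulate_kinetics(default_network(), cc, totals_vector(10, 10, 0))
  expect_equal(ks["X_10", "concentration"],
               oracle_quadratic_bound(0.1, 10, 10), tolerance = 1e-6)
})

test_that("mass balances and equilibrium relations hold at random draws", {
  set.seed(202)
  net <- default_network()
  for (i in 1:40) {
    cc <- close_cycles(net, random_constants())
    tot <- totals_vector(10 ^ runif(1, -3, 3), 10 ^ runif(1, -3, 3),
                         10 ^ runif(1, -3, 3))
    st <- solve_equilibrium(net, cc, tot)
    expect_lt(max(attr(st, "balance_residuals")), 1e-9)
    expect_lt(max(attr(st, "equilibrium_residuals")), 1e-9)
    expect_true(all(st$concentration >= 0))
  }
})

test_that("equilibrium solver agrees with kinetic integration", {
  set.seed(303)
  net <- default_network()
  for (i in 1:10) {
    cc <- close_cycles(net, random_constants())
    tot <- totals_vector(10 ^ runif(1, -3, 3), 10 ^ runif(1, -3, 3),
                         10 ^ runif(1, -3, 3))
    st <- solve_equilibrium(net, cc, tot)
    ks <- simulate_kinetics(net, cc, tot)
    expect_true(attr(ks, "converged"))
    scale <- max(unclass(tot))
    rel <- abs(st$concentration - ks$concentration) /
      pmax(pmax(st$concentration, ks$concentration), 1e-9 * scale)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("bound DNA is monotone in totals and in the constants", {
  net <- default_network()
  bound_p <- function(K12_mult = 1, dna = 20) {
    cc <- make_closed(0.002, 0.075, 0.05, 0.05,
                      K_00_12 = K12_mult * 100 * 0.002 * 0.075,
                      K_00_22 = 10 * 0.075^2)
    st <- solve_equilibrium(net, cc, totals_vector(dna, 10, 30))
    observable_fraction(st, "P") * dna
  }
  # non-decreasing in total DNA (bound amount, not fraction)
  b_dna <- vapply(c(1, 5, 20, 80, 320), function(d) bound_p(dna = d),
                  numeric(1))
  expect_true(all(diff(b_dna) >= -1e-12))
  # non-decreasing in the ternary constant
  b_k <- vapply(c(0.1, 1, 10, 100), function(m) bound_p(K12_mult = m),
                numeric(1))
  expect_true(all(diff(b_k) >= -1e-12))
})

test_that("without dimers and cooperativity the sites are independent", {
  # K_D1, K_D2 negligible and omega = 1: the P-bound fraction factorizes
  # into independent single-site occupancies of the free concentrations
  net <- default_network()
  K10 <- 0.01; K02 <- 0.05
  cc <- make_closed(K10, K02, 1e-12, 1e-12,
                    K_00_12 = K10 * K02, K_00_22 = K02^2)
  st <- solve_equilibrium(net, cc, totals_vector(5, 8, 12))
  p <- st["X_1", "concentration"]
  r <- st["X_2", "concentration"]
  expected <- K10 * p / (1 + K10 * p + K02 * r)
  expect_equal(observable_fraction(st, "P"), expected, tolerance = 1e-9)
})

test_that("observable fraction equals the composition-scan sum", {
  set.seed(404)
  net <- default_network()
  for (i in 1:10) {
    cc <- close_cycles(net, random_constants(1e-2, 1e2))
    tot <- totals_vector(10 ^ runif(1, -1, 2), 10 ^ runif(1, -1, 2),
                         10 ^ runif(1, -1, 2))
    st <- solve_equilibrium(net, cc, tot)
    explicit_p <- sum(st[c("X_10", "X_12", "X_120", "X_012", "X_210"),
                         "concentration"]) / unclass(tot)[["total_dna"]]
    expect_equal(observable_fraction(st, "P"), explicit_p,
                 tolerance = 1e-12)
    scan_r <- sum(st$concentration[st$n_dna > 0 & st$n_l2 > 0]) /
      unclass(tot)[["total_dna"]]
    expect_equal(observable_fraction(st, "R"), scan_r, tolerance = 1e-12)
    expect_gte(observable_fraction(st, "P"), 0)
    expect_lte(observable_fraction(st, "P"), 1 + 1e-12)
  }
})

test_that("zero DNA makes the bound fraction undefined", {
  cc <- make_closed(0.1, 0.2, 0.05, 0.02, K_00_12 = 2, K_00_22 = 0.008)
  st <- solve_equilibrium(default_network(), cc, totals_vector(0, 10, 10))
  expect_error(observable_fraction(st, "P"), "undefined")
})

test_that("species states export as TSV", {
  cc <- make_closed(0.1, 0.2, 0.05, 0.02, K_00_12 = 2, K_00_22 = 0.008)
  st <- solve_equilibrium(default_network(), cc, totals_vector(10, 5, 20))
  f <- tempfile(fileext = ".tsv")
  write_species_state(st, f)
  back <- read.delim(f)
  expect_identical(back$species_id, st$species_id)
  expect_equal(back$concentration, st$concentration, tolerance = 1e-12)
})
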