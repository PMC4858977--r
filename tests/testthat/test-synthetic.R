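test_that("substitution libraries enumerate 3L + 1 sequences", {
  ppre <- substitution_library(response_elements["PPRE"], "PPRE")
  expect_length(ppre, 3 * 18 + 1)
  pal3 <- substitution_library(response_elements["PAL3"], "PAL3")
  expect_length(pal3, 3 * 20 + 1)
  expect_true("PPRE_ref" %in% names(ppre))
  expect_equal(as.character(ppre[["PPRE_ref"]]),
               unname(response_elements["PPRE"]))
  # every non-reference member differs from the reference at one position
  ref <- strsplit(unname(response_elements["PPRE"]), "")[[1]]
  for (nm in setdiff(names(ppre), "PPRE_ref")) {
    v <- strsplit(as.character(ppre[[nm]]), "")[[1]]
    expect_identical(sum(v != ref), 1L)
  }
  expect_false(anyDuplicated(as.character(ppre)) > 0)
  one <- substitution_library("A", "x")
  expect_setequal(as.character(one), c("A", "C", "G", "T"))
  expect_error(substitution_library("ACGX"), "input error")
})

test_that("noiseless one-site simulation equals the quadratic closed form", {
  net <- build_network()
  # RXRalpha absent: the readout is the plain one-site PPARgamma curve
  K10 <- 0.02
  truth <- ground_truth(
    constants = list(s = equilibrium_constants(K10, 0.075, 0.05, 0.05,
                                               K_00_12 = 1e-9,
                                               K_00_22 = 1e-9)),
    design = data.frame(total_dna_nM = c(1, 5, 20, 80),
                        total_p_nM = 10, total_r_nM = 0),
    gain = 2, noise_cv = 0, noise_floor = 0)
  ds <- simulate_binding_dataset(truth, net)
  expect_equal(ds$signal,
               2 * oracle_quadratic_bound(K10, 10, c(1, 5, 20, 80)),
               tolerance = 1e-9)
})

test_that("gain scales signals exactly and seeds reproduce tables", {
  net <- build_network()
  mk <- function(gain, seed = 17) ground_truth(
    constants = list(s = default_constants()), gain = gain,
    noise_cv = 0.02, noise_floor = 0, seed = seed)
  d1 <- simulate_binding_dataset(mk(2), net)
  d2 <- simulate_binding_dataset(mk(4), net)
  expect_equal(d2$signal, 2 * d1$signal, tolerance = 1e-12)
  expect_identical(simulate_binding_dataset(mk(2), net), d1)
  d3 <- simulate_binding_dataset(mk(2, seed = 18), net)
  expect_false(identical(d3$signal, d1$signal))
})

test_that("planted regions are reproducible and class-balanced", {
  P <- table1_fixture()$KDoD
  r1 <- plant_motif_regions(P, 30, 20, region_length = 200, seed = 5)
  r2 <- plant_motif_regions(P, 30, 20, region_length = 200, seed = 5)
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))
  expect_identical(sum(r1$labels == 1), 30L)
  expect_identical(sum(r1$labels == 0), 20L)
  expect_true(all(Biostrings::width(r1$sequences) == 200))
  expect_error(plant_motif_regions(P, 0, 10), "non-empty")
  expect_error(plant_motif_regions(P, 5, 5, region_length = 10),
               "shorter than motif")
  expect_error(plant_motif_regions(P, 5, 5, fidelity = 2), "fidelity")
})

test_that("full-fidelity planting reproduces the consensus frequency", {
  # sharp 4-mer: P(exact consensus) = 0.94^4; check the empirical rate
  m <- matrix(0.02, 4, 4)
  m[cbind(1:4, c(1, 2, 3, 4))] <- 0.94
  P <- probability_matrix(m, tol = 1e-9)
  rs <- plant_motif_regions(P, n_pos = 400, n_neg = 1, region_length = 30,
                            fidelity = 1, seed = 31)
  hits <- vapply(as.character(rs$sequences[rs$labels == 1]),
                 function(s) grepl("ACGT", s), logical(1))
  p_expect <- 0.94^4
  se <- sqrt(p_expect * (1 - p_expect) / 400)
  # planted instance itself matches at rate p; background can also contain
  # the 4-mer, so the observed rate may only exceed the planting rate
  expect_gt(mean(hits), p_expect - 4 * se)
  # zero fidelity plants pure background: consensus appears at chance level
  rs0 <- plant_motif_regions(P, n_pos = 400, n_neg = 1, region_length = 30,
                             fidelity = 0, seed = 31)
  hits0 <- vapply(as.character(rs0$sequences[rs0$labels == 1]),
                  function(s) grepl("ACGT", s), logical(1))
  expect_lt(mean(hits0), 0.3)
})

test_that("planted omega is recovered end to end at low noise", {
  net <- build_network()
  set.seed(140)
  log_ratios <- vapply(1:5, function(i) {
    w <- 10 ^ runif(1, 1, 2.5)
    w22 <- 10 ^ runif(1, 0, 1.5)
    truth <- ground_truth(
      constants = list(s = default_constants(omega_12 = w,
                                             omega_22 = w22)),
      noise_cv = 0.01, noise_floor = 0, seed = sample.int(1e6, 1))
    ds <- simulate_binding_dataset(truth, net)
    f <- fit_heterodimer(ds, equilibrium_constants(0.002, 0.075,
                                                   0.05, 0.05),
                         network = net)
    abs(log(omega(f$parameters[["K_00_12"]], 0.002, 0.075) / w))
  }, numeric(1))
  expect_lt(median(log_ratios), 0.1)
})

test_that("the default PPRE library generator plants positive cooperativity", {
  # a small slice of the substitution library: all planted omega > 1 and
  # the recovered map reports positive cooperativity throughout
  set.seed(150)
  omegas <- 10 ^ runif(6, 1, 2.5)
  fits <- c(list(PPRE_ref = default_constants(omega_12 = 100)),
            setNames(lapply(omegas, function(w)
              default_constants(omega_12 = w)),
              sprintf("PPRE_p%d%s>%s", 1:6, c("A", "A", "A", "C", "T", "A"),
                      c("C", "G", "T", "A", "G", "C"))))
  map <- cooperativity_map(fits, "PPRE_ref")
  expect_true(all(map$omega_12 > 1))
  expect_true(all(classify_cooperativity(map$omega_12) == "positive"))
})
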