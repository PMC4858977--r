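# -- synthetic data generation ------------------------------------------------

#' Canonical response-element sequences
#'
#' The PPRE direct-repeat element (two AGGTCA half-sites separated by one
#' nucleotide, preceded by the 5'-AAACT extension contacted by PPARgamma)
#' and the palindromic PAL3 element bound by monomeric PPARgamma.
#'
#' @format Named character vector with elements \code{PPRE} (18 nt) and
#'   \code{PAL3} (20 nt).
#' @export
response_elements <- c(
  PPRE = "AAACTAGGTCAAAGGTCA",
  PAL3 = "AAACTAGGTCACCGTGACCT")

#' Single-base substitution library of a sequence
#'
#' Generates every variant obtained by substituting one nucleotide of the
#' element at a time to all possible alternatives, plus the unmodified
#' reference (flagged by name). An L-mer yields 3L variants + 1 reference.
#'
#' @param reference ACGT character string (or \code{DNAString}).
#' @param name Prefix used in variant names; variants are named
#'   \code{<name>_p<position><ref>><base>}, the reference \code{<name>_ref}.
#' @return A \code{\link[Biostrings]{DNAStringSet}} of 3L + 1 sequences.
#' @examples
#' lib <- substitution_library("AAACTAGGTCAAAGGTCA", "PPRE")
#' length(lib)   # 55
#' @export
substitution_library <- function(reference, name = "seq") {
  reference <- toupper(as.character(reference))
  chars <- strsplit(reference, "")[[1]]
  if (!all(chars %in% DNA_BASES))
    stop("input error: reference must contain only A, C, G, T",
         call. = FALSE)
  seqs <- c(setNames(reference, paste0(name, "_ref")))
  for (i in seq_along(chars)) {
    for (b in setdiff(DNA_BASES, chars[i])) {
      v <- chars; v[i] <- b
      seqs[sprintf("%s_p%d%s>%s", name, i, chars[i], b)] <-
        paste(v, collapse = "")
    }
  }
  Biostrings::DNAStringSet(seqs)
}

#' Ground truth for a simulated binding experiment
#'
#' Bundles everything needed to generate a reproducible MITOMI-style
#' dataset: per-sequence equilibrium constants, the instrument gain, the
#' noise model (multiplicative coefficient of variation plus a small
#' additive floor, matching fluorescence readouts) and the concentration
#' design.
#'
#' The default constants describe the reference PPRE conditions: weak
#' monomeric PPARgamma binding (K_00_10 = 0.002/nM), moderate RXRalpha
#' site binding (K_00_02 = 0.075/nM), solution dimerization at 0.05/nM,
#' and strongly positive heterodimer cooperativity (omega_12 = 100,
#' omega_22 = 10).
#'
#' @param constants Either one \code{\link{equilibrium_constants}} set or a
#'   named list of them (one per sequence).
#' @param design Data frame with columns \code{total_dna_nM},
#'   \code{total_p_nM}, \code{total_r_nM}.
#' @param gain Fluorescence units per nM of bound DNA.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param noise_floor Standard deviation of the additive noise floor, in
#'   signal units.
#' @param seed Integer seed making the dataset reproducible.
#' @return A list of class \code{ground_truth}.
#' @export
ground_truth <- function(constants = default_constants(),
                         design = design_titration_grid(),
                         gain = 2, noise_cv = 0.01, noise_floor = 0.005,
                         seed = 17L) {
  if (inherits(constants, "equilibrium_constants"))
    constants <- list(seq1 = constants)
  stopifnot(length(constants) > 0,
            all(vapply(constants, inherits, logical(1),
                       "equilibrium_constants")),
            !is.null(names(constants)),
            is.data.frame(design), nrow(design) > 0,
            all(c("total_dna_nM", "total_p_nM", "total_r_nM") %in%
                  names(design)),
            gain > 0, noise_cv >= 0, noise_floor >= 0)
  structure(list(constants = constants, design = design, gain = gain,
                 noise_cv = noise_cv, noise_floor = noise_floor,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Reference-condition equilibrium constants
#'
#' @param omega_12 Heterodimer cooperativity factor planted on the sequence.
#' @param omega_22 Homodimer cooperativity factor.
#' @param K_00_10,K_00_02,K_D1,K_D2 Binary constants (1/nM).
#' @return An \code{\link{equilibrium_constants}} set with
#'   \code{K_00_12 = omega_12 * K_00_10 * K_00_02} and
#'   \code{K_00_22 = omega_22 * K_00_02^2}.
#' @export
default_constants <- function(omega_12 = 100, omega_22 = 10,
                              K_00_10 = 0.002, K_00_02 = 0.075,
                              K_D1 = 0.05, K_D2 = 0.05) {
  equilibrium_constants(K_00_10, K_00_02, K_D1, K_D2,
                        K_00_12 = omega_12 * K_00_10 * K_00_02,
                        K_00_22 = omega_22 * K_00_02^2)
}

#' Titration designs
#'
#' \code{design_titration_grid} is the cooperativity-mode design: eight DNA
#' concentrations (log-spaced 1-630 nM) crossed with three PPARgamma levels
#' at a fixed RXRalpha excess. \code{design_relative_affinity} is the
#' screening-mode design: four DNA concentrations in the sub-saturation
#' linear range at one protein level.
#'
#' @param dna_nM,p_nM,r_nM Concentration grids (nM).
#' @return Data frame with columns \code{total_dna_nM}, \code{total_p_nM},
#'   \code{total_r_nM}.
#' @export
design_titration_grid <- function(dna_nM = 10 ^ seq(0, 2.8, length.out = 8),
                                  p_nM = c(2.5, 5, 10), r_nM = 30) {
  expand.grid(total_dna_nM = dna_nM, total_p_nM = p_nM, total_r_nM = r_nM,
              KEEP.OUT.ATTRS = FALSE)
}

#' @rdname design_titration_grid
#' @export
design_relative_affinity <- function(dna_nM = c(1, 2, 4, 8), p_nM = 10,
                                     r_nM = 30) {
  expand.grid(total_dna_nM = dna_nM, total_p_nM = p_nM, total_r_nM = r_nM,
              KEEP.OUT.ATTRS = FALSE)
}

#' Simulate a MITOMI-style binding dataset
#'
#' For every sequence and design point the species network is solved at
#' equilibrium and the readout signal is
#' gain x bound fraction x total DNA x (1 + eps) + floor noise,
#' with eps Gaussian of standard deviation \code{noise_cv}. With
#' \code{noise_cv = 0} and \code{noise_floor = 0} the signals are the exact
#' equilibrium predictions. Identical seeds give identical tables.
#'
#' @param truth A \code{\link{ground_truth}}.
#' @param network A \code{\link{build_network}} result.
#' @param readout Immobilized ligand ("P" or "R").
#' @param replicate Replicate identifier recorded in the table.
#' @return Data frame in the binding-table schema: \code{sequence_id},
#'   \code{total_dna_nM}, \code{total_p_nM}, \code{total_r_nM},
#'   \code{signal}, \code{replicate}.
#' @export
simulate_binding_dataset <- function(truth, network = build_network(),
                                     readout = "P", replicate = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed)
  out <- lapply(names(truth$constants), function(id) {
    cc <- close_cycles(network, truth$constants[[id]])
    b <- tryCatch(
      .bound_dna_batch(network, cc, truth$design, readout = readout),
      error = function(e)
        stop("generation error for sequence '", id, "': ",
             conditionMessage(e), call. = FALSE))
    n <- length(b)
    eps <- if (truth$noise_cv > 0) rnorm(n, 0, truth$noise_cv) else 0
    floor_noise <- if (truth$noise_floor > 0)
      rnorm(n, 0, truth$noise_floor) else 0
    data.frame(sequence_id = id,
               total_dna_nM = truth$design$total_dna_nM,
               total_p_nM = truth$design$total_p_nM,
               total_r_nM = truth$design$total_r_nM,
               signal = truth$gain * b * (1 + eps) + floor_noise,
               replicate = replicate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plant motif instances in synthetic regions
#'
#' Builds a labelled region set for motif evaluation: positives are uniform
#' background sequence with one motif instance sampled from the probability
#' matrix (blended with background according to \code{fidelity}) inserted at
#' a random offset; negatives are pure background. This mirrors the
#' geometry of peak-centred positive regions versus downstream negative
#' regions, without any genomic structure.
#'
#' @param P A \code{prob_matrix} to plant.
#' @param n_pos,n_neg Number of positive / negative regions (both > 0).
#' @param region_length Region length in bp (>= motif length).
#' @param fidelity In [0, 1]: 1 samples straight from P, 0 from background.
#' @param seed Integer seed.
#' @return A list of class \code{region_set}: \code{sequences}
#'   (\code{DNAStringSet}), \code{labels} (1 positive / 0 negative),
#'   \code{motif_start} (1-based plant offset, NA for negatives).
#' @export
plant_motif_regions <- function(P, n_pos, n_neg, region_length = 200,
                                fidelity = 1, seed = 17L) {
  stopifnot(inherits(P, "prob_matrix"))
  if (n_pos < 1 || n_neg < 1)
    stop("input error: both classes must be non-empty for evaluation",
         call. = FALSE)
  L <- nrow(P)
  if (region_length < L)
    stop("input error: region_length (", region_length,
         ") shorter than motif (", L, ")", call. = FALSE)
  if (fidelity < 0 || fidelity > 1)
    stop("input error: fidelity must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  bg <- attr(P, "background")
  blend <- fidelity * unclass(P) +
    (1 - fidelity) * matrix(bg, L, 4, byrow = TRUE)
  rand_bg <- function(n) paste(sample(DNA_BASES, n, replace = TRUE,
                                      prob = bg), collapse = "")
  positives <- vapply(seq_len(n_pos), function(i) {
    s <- strsplit(rand_bg(region_length), "")[[1]]
    inst <- vapply(seq_len(L), function(j)
      sample(DNA_BASES, 1, prob = blend[j, ]), character(1))
    off <- sample.int(region_length - L + 1, 1)
    s[off:(off + L - 1)] <- inst
    paste(s, collapse = "")
  }, character(1))
  # record plant offsets (regenerate deterministically alongside)
  negatives <- vapply(seq_len(n_neg), function(i) rand_bg(region_length),
                      character(1))
  seqs <- Biostrings::DNAStringSet(c(positives, negatives))
  names(seqs) <- c(sprintf("pos_%03d", seq_len(n_pos)),
                   sprintf("neg_%03d", seq_len(n_neg)))
  structure(list(sequences = seqs,
                 labels = c(rep(1L, n_pos), rep(0L, n_neg)),
                 region_length = region_length, fidelity = fidelity,
                 provenance = "synthetic"),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set:", sum(x$labels == 1), "positive /", sum(x$labels == 0),
      "negative regions of", x$region_length, "bp (", x$provenance, ")\n")
  invisible(x)
}

#' Packaged PPARgamma::RXRalpha specificity matrices
#'
#' Loads the two published 15-position probability matrices of
#' PPARgamma:RXRalpha binding to PPRE: one derived from one-site Kd values
#' and one from the cooperativity-inclusive K_DoD constants. They ship with
#' the package as MEME minimal files.
#'
#' @return Named list with \code{prob_matrix} elements \code{Kd} and
#'   \code{KDoD}.
#' @examples
#' m <- table1_fixture()
#' m$Kd[1, ]   # 0.110 0.411 0.360 0.120
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "pparg_rxra_pssms.meme",
                      package = "coopbind")
  if (path == "")  # package not installed (e.g. sourced tree)
    path <- file.path("inst", "extdata", "pparg_rxra_pssms.meme")
  motifs <- read_meme(path)
  list(Kd = motifs[["Kd_PPARg_RXRa"]], KDoD = motifs[["KDoD_PPARg_RXRa"]])
}
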