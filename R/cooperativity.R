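# -- cooperativity metrics ----------------------------------------------------

#' Cooperativity factor of a ternary complex
#'
#' The ratio of the overall ternary-complex association constant to the
#' product of the two corresponding binary constants:
#' omega = K_ternary / (K_a * K_b). Values above one indicate positive
#' cooperativity (the second ligand binds more tightly once the first is in
#' place), values below one negative cooperativity; omega = 1 is the
#' additive, non-cooperative case. For the heterodimer system
#' omega_12 = K_00_12 / (K_00_10 * K_00_02) and
#' omega_22 = K_00_22 / K_00_02^2.
#'
#' @param K_ternary Overall association constant of the ternary complex
#'   (1/nM^2).
#' @param K_a,K_b The two binary association constants (1/nM).
#' @return The dimensionless cooperativity factor.
#' @examples
#' omega(6, 2, 3)          # 1: additive
#' omega(600, 2, 3)        # 100: strong positive cooperativity
#' @export
omega <- function(K_ternary, K_a, K_b) {
  if (any(c(K_ternary, K_a, K_b) <= 0) ||
      any(!is.finite(c(K_ternary, K_a, K_b))))
    stop("all constants must be strictly positive", call. = FALSE)
  K_ternary / (K_a * K_b)
}

#' Classify a cooperativity factor
#'
#' @param omega Positive cooperativity factor.
#' @return \code{"positive"} if omega > 1, \code{"negative"} if omega < 1,
#'   \code{"none"} at exactly 1.
#' @export
classify_cooperativity <- function(omega) {
  stopifnot(all(omega > 0))
  ifelse(omega > 1, "positive", ifelse(omega < 1, "negative", "none"))
}

#' Cooperativity summary of a closed constant set
#'
#' Computes both cooperativity factors and the apparent heterodimer-on-DNA
#' constant from a full constant set.
#'
#' @param constants An \code{\link{equilibrium_constants}} set with all six
#'   values present.
#' @return A list of class \code{cooperativity_result}: \code{omega_12},
#'   \code{omega_22}, \code{K_DoD}, \code{classification}.
#' @export
cooperativity <- function(constants) {
  stopifnot(inherits(constants, "equilibrium_constants"))
  v <- constants$values
  if (any(is.na(v))) stop("all six constants must be set", call. = FALSE)
  o12 <- omega(v[["K_00_12"]], v[["K_00_10"]], v[["K_00_02"]])
  o22 <- omega(v[["K_00_22"]], v[["K_00_02"]], v[["K_00_02"]])
  kd <- if (inherits(constants, "closed_constants")) k_dod(constants)$K_DoD
        else v[["K_00_12"]]
  structure(list(omega_12 = o12, omega_22 = o22, K_DoD = kd,
                 classification = classify_cooperativity(o12)),
            class = "cooperativity_result")
}

#' @export
print.cooperativity_result <- function(x, ...) {
  cat(sprintf("omega_12 = %.4g (%s), omega_22 = %.4g, K_DoD = %.4g\n",
              x$omega_12, x$classification, x$omega_22, x$K_DoD))
  invisible(x)
}

#' Apparent heterodimer-on-DNA association constant
#'
#' K_DoD is the product of the binding affinities along each pathway that
#' assembles the fully engaged heterodimer ternary complex on DNA. Because
#' the constant set is thermodynamically cycle-closed, every pathway yields
#' the same product — the order of binding events does not matter — and that
#' common value is K_DoD (units 1/nM^2). The audited pathways are:
#' PPARgamma binds first and RXRalpha joins; RXRalpha binds first (right
#' site) and PPARgamma joins; the solution heterodimer tethers via RXRalpha
#' (right site) and PPARgamma then engages; and the solution heterodimer
#' tethers via PPARgamma (left site) and RXRalpha then engages.
#'
#' @param constants A cycle-closed constant set from
#'   \code{\link{close_cycles}}.
#' @param tol Maximum tolerated relative spread across pathway products.
#' @return A list of class \code{k_dod_result}: \code{K_DoD} and
#'   \code{pathways} (data frame of per-pathway step constants and products).
#' @examples
#' net <- build_network()
#' cc <- close_cycles(net, equilibrium_constants(2, 3, 0.1, 0.1,
#'                                               K_00_12 = 6, K_00_22 = 9))
#' k_dod(cc)$K_DoD     # 6: the omega = 1 product 2 x 3
#' @export
k_dod <- function(constants, tol = 1e-12) {
  stopifnot(inherits(constants, "closed_constants"))
  rx <- constants$derived
  kval <- function(label) {
    i <- match(label, rx$label)
    if (is.na(i)) stop("reaction not in network: ", label, call. = FALSE)
    rx$value[i]
  }
  paths <- list(
    "monomer-first: P then R" =
      c("X_0 + X_1 -> X_10", "X_10 + X_2 -> X_12"),
    "monomer-first: R then P" =
      c("X_0 + X_2 -> X_02", "X_02 + X_1 -> X_12"),
    "dimer-first: tether via R" =
      c("X_1 + X_2 -> X_D1", "X_0 + X_D1 -> X_012", "X_012 -> X_12"),
    "dimer-first: tether via P" =
      c("X_1 + X_2 -> X_D1", "X_0 + X_D1 -> X_210", "X_210 -> X_12"))
  products <- vapply(paths, function(p) prod(vapply(p, kval, numeric(1))),
                     numeric(1))
  spread <- (max(products) - min(products)) / max(products)
  if (spread > tol)
    stop("pathway products disagree (relative spread ", signif(spread, 3),
         "): ", paste(sprintf("%s = %.6g", names(products), products),
                      collapse = "; "), call. = FALSE)
  structure(list(K_DoD = unname(products[1]),
                 pathways = data.frame(pathway = names(paths),
                                       product = unname(products),
                                       steps = vapply(paths, paste,
                                                      character(1),
                                                      collapse = "; "),
                                       row.names = NULL)),
            class = "k_dod_result")
}

#' @export
print.k_dod_result <- function(x, ...) {
  cat(sprintf("K_DoD = %.6g (pathway-invariant over %d formation routes)\n",
              x$K_DoD, nrow(x$pathways)))
  invisible(x)
}

#' Binding free-energy difference between two sites
#'
#' ddG = -RT ln(K_variant / K_reference), in kcal/mol: positive when the
#' variant binds more weakly than the reference. Antisymmetric under
#' exchanging variant and reference, and additive along chains of variants.
#'
#' @param K_variant,K_reference Positive association constants (any common
#'   unit).
#' @param RT Thermal energy in kcal/mol; default 0.593 (298 K).
#' @param variant_id,reference_id Optional sequence identifiers carried in
#'   the result.
#' @return A list of class \code{energy_difference} with elements
#'   \code{ddG} (kcal/mol), \code{RT}, and the two identifiers.
#' @examples
#' ddG(0.01, 0.1)$ddG     # +RT ln 10: tenfold weaker binding
#' @export
ddG <- function(K_variant, K_reference, RT = 0.593,
                variant_id = NA_character_, reference_id = NA_character_) {
  if (any(c(K_variant, K_reference, RT) <= 0))
    stop("constants and RT must be strictly positive", call. = FALSE)
  structure(list(ddG = -RT * log(K_variant / K_reference), RT = RT,
                 variant_sequence_id = variant_id,
                 reference_sequence_id = reference_id),
            class = "energy_difference")
}

#' @export
print.energy_difference <- function(x, ...) {
  cat(sprintf("ddG = %+.4g kcal/mol (RT = %.3g)\n", x$ddG, x$RT))
  invisible(x)
}

#' Affinity-ratio proxy for cooperativity
#'
#' When full titrations are unavailable and only relative affinities (linear
#' slopes) were measured, the cooperativity factor is approximated by sigma,
#' the ratio of the heterodimer's relative affinity to a monomer's relative
#' affinity. As printed convention (orientation = which factor was tethered
#' to the surface): with PPARgamma tethered, sigma = heterodimer affinity /
#' RXRalpha monomer affinity; with RXRalpha tethered, sigma = heterodimer
#' affinity / PPARgamma monomer affinity. Set \code{partner_of_tethered =
#' FALSE} to divide instead by the tethered factor's own monomer affinity
#' (the "affinity change upon addition of the partner" reading).
#'
#' @param affinity_heterodimer Relative affinity (slope) of the heterodimer.
#' @param affinity_monomer Relative affinity of the monomer in the
#'   denominator; must be > 0.
#' @param tethered Which factor was immobilized ("P" or "R"); recorded in
#'   the result.
#' @param partner_of_tethered Logical; TRUE (default) for the printed
#'   convention where the denominator is the partner monomer's affinity.
#' @return A list of class \code{sigma_proxy}: \code{sigma},
#'   \code{tethered}, \code{denominator}.
#' @export
sigma_proxy <- function(affinity_heterodimer, affinity_monomer,
                        tethered = c("P", "R"),
                        partner_of_tethered = TRUE) {
  tethered <- match.arg(tethered)
  if (!is.finite(affinity_monomer) || affinity_monomer <= 0)
    stop("undefined ratio: monomer affinity must be positive", call. = FALSE)
  denom_factor <- if (partner_of_tethered)
    setdiff(c("P", "R"), tethered) else tethered
  structure(list(sigma = affinity_heterodimer / affinity_monomer,
                 tethered = tethered, denominator = denom_factor),
            class = "sigma_proxy")
}

#' @export
print.sigma_proxy <- function(x, ...) {
  cat(sprintf("sigma = %.4g (tethered %s, denominator: %s monomer)\n",
              x$sigma, x$tethered, x$denominator))
  invisible(x)
}

#' Per-variant cooperativity map
#'
#' Assembles the table behind a substitution-library cooperativity heatmap:
#' one row per single-base variant with its cooperativity factors, K_DoD
#' and the binding free-energy difference of the heterodimer constant
#' relative to the reference sequence.
#'
#' @param fits Named list (by sequence id) of full
#'   \code{\link{equilibrium_constants}} sets, one per variant; names follow
#'   the \code{\link{substitution_library}} convention
#'   \code{<name>_p<position><ref>><base>} with a \code{<name>_ref} entry.
#' @param reference_id Identifier of the reference sequence in \code{fits}.
#' @param RT Thermal energy (kcal/mol) for the ddG column.
#' @return Data frame: sequence_id, position, substituted_base, omega_12,
#'   omega_22, K_DoD, ddG.
#' @export
cooperativity_map <- function(fits, reference_id, RT = 0.593) {
  stopifnot(is.list(fits), reference_id %in% names(fits))
  ref_k <- fits[[reference_id]]$values[["K_00_12"]]
  rows <- lapply(names(fits), function(id) {
    co <- cooperativity(fits[[id]])
    m <- regmatches(id, regexec("_p(\\d+)[ACGT]>([ACGT])$", id))[[1]]
    data.frame(sequence_id = id,
               position = if (length(m)) as.integer(m[2]) else NA_integer_,
               substituted_base = if (length(m)) m[3] else NA_character_,
               omega_12 = co$omega_12, omega_22 = co$omega_22,
               K_DoD = co$K_DoD,
               ddG = ddG(fits[[id]]$values[["K_00_12"]], ref_k, RT)$ddG,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
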