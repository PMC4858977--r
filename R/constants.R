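# -- equilibrium constant sets ------------------------------------------------

#' Assemble a set of primary association constants
#'
#' The six primary constants of the heterodimer model, all association
#' constants in inverse concentration units (default 1/nM):
#' \describe{
#'   \item{K_00_10}{first ligand (PPARgamma) binding the left DNA site.}
#'   \item{K_00_02}{second ligand (RXRalpha) binding either DNA site (the
#'     two half-sites are taken to have equal affinity).}
#'   \item{K_D1}{solution heterodimerization (PPARgamma:RXRalpha).}
#'   \item{K_D2}{solution homodimerization (RXRalpha:RXRalpha).}
#'   \item{K_00_12}{overall association of DNA + both ligands into the fully
#'     engaged heterodimer ternary complex (units 1/nM^2).}
#'   \item{K_00_22}{overall association into the homodimer ternary complex
#'     (units 1/nM^2).}
#' }
#' With the four binary constants fixed from independent measurements, the
#' two overall ternary constants are the model's free parameters.
#'
#' @param K_00_10,K_00_02,K_D1,K_D2,K_00_12,K_00_22 Positive numerics
#'   (\code{K_00_12}/\code{K_00_22} may be \code{NA} before fitting).
#' @param unit Concentration unit the constants refer to.
#' @return An object of class \code{equilibrium_constants}.
#' @export
equilibrium_constants <- function(K_00_10, K_00_02, K_D1, K_D2,
                                  K_00_12 = NA_real_, K_00_22 = NA_real_,
                                  unit = "nM") {
  vals <- setNames(as.numeric(c(K_00_10, K_00_02, K_D1, K_D2,
                                K_00_12, K_00_22)), .primary_constants)
  known <- vals[!is.na(vals)]
  if (any(known <= 0) || any(!is.finite(known)))
    stop("all association constants must be strictly positive and finite",
         call. = FALSE)
  structure(list(values = vals, unit = unit), class = "equilibrium_constants")
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat("Equilibrium constants (1/", x$unit, "):\n", sep = "")
  print(x$values)
  if (!is.null(x$derived))
    cat("cycle-closed:", nrow(x$derived), "elementary constants derived\n")
  invisible(x)
}

#' Derive every elementary constant by thermodynamic cycle closure
#'
#' Evaluates the constant of each elementary reaction in the network from the
#' primary set. Because each constant is an exact monomial in the primaries,
#' the product of constants around any closed reaction cycle is one by
#' construction; this function materializes the numeric values and checks
#' positivity. Singly-tethered dimer species contact DNA with the unmodified
#' monomer constant of the contacting subunit; cooperativity enters only in
#' the fully engaged ternary complexes.
#'
#' @param network A \code{\link{build_network}} result.
#' @param primary An \code{\link{equilibrium_constants}} set with all values
#'   required by the network present and positive.
#' @return The constant set, augmented with \code{derived} (data frame of
#'   per-reaction constants) and \code{formation} (named vector of overall
#'   formation constants per complex species), class
#'   \code{c("closed_constants", "equilibrium_constants")}.
#' @examples
#' net <- build_network()
#' ks <- equilibrium_constants(0.1, 0.2, 0.05, 0.02,
#'                             K_00_12 = 2, K_00_22 = 0.008)
#' cc <- close_cycles(net, ks)
#' head(cc$derived)
#' @export
close_cycles <- function(network, primary) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(primary, "equilibrium_constants"))
  needed <- Reduce(`+`, lapply(c(network$formation,
                                 network$reaction_monomials), abs))
  needed <- .primary_constants[needed > 0]
  vals <- primary$values[needed]
  if (any(is.na(vals)) || any(vals <= 0))
    stop("cycle closure needs strictly positive values for: ",
         paste(needed, collapse = ", "), call. = FALSE)
  ev <- function(m) .mono_eval(m, primary$values[!is.na(primary$values)])
  derived <- network$reactions
  derived$value <- vapply(network$reaction_monomials, ev, numeric(1))
  formation <- vapply(network$formation, ev, numeric(1))
  out <- primary
  out$derived <- derived
  out$formation <- formation
  out$network_species <- network$species$id
  class(out) <- c("closed_constants", "equilibrium_constants")
  out
}

#' Concentration totals of the three components
#'
#' Mass-balance inputs for the equilibrium solver, in the concentration unit
#' of the constant set (default nM).
#'
#' @param total_dna,total_p,total_r Non-negative total concentrations of the
#'   DNA element, first ligand (PPARgamma) and second ligand (RXRalpha).
#' @return Named numeric vector of class \code{totals_vector}.
#' @export
totals_vector <- function(total_dna, total_p = 0, total_r = 0) {
  v <- c(total_dna = total_dna, total_p = total_p, total_r = total_r)
  if (any(v < 0) || any(!is.finite(v)))
    stop("totals must be finite and non-negative", call. = FALSE)
  structure(v, class = "totals_vector")
}
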