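#' @importFrom stats optim optimize rnorm runif setNames coef lm sd median
#' @importFrom utils read.delim write.table head tail
NULL

# Primary association constants of the two-ligand / two-site system.
# The four binaries are measured independently; the two overall ternary
# constants are the free parameters of the heterodimer model.
.primary_constants <- c("K_00_10", "K_00_02", "K_D1", "K_D2",
                        "K_00_12", "K_00_22")

# -- monomial algebra over the primary constants -----------------------------
# Every derived constant is a Laurent monomial in the six primaries; keeping
# integer exponents makes cycle closure exact rather than a numerical check.

.mono <- function(...) {
  e <- setNames(integer(length(.primary_constants)), .primary_constants)
  args <- c(...)
  if (length(args)) {
    stopifnot(all(names(args) %in% .primary_constants))
    e[names(args)] <- e[names(args)] + as.integer(args)
  }
  e
}

.mono_mul <- function(a, b) a + b
.mono_div <- function(a, b) a - b

.mono_eval <- function(m, values) {
  prod(unlist(values)[names(m)] ^ m)
}

.mono_format <- function(m) {
  nz <- m[m != 0L]
  if (!length(nz)) return("1")
  paste(vapply(seq_along(nz), function(i) {
    if (nz[i] == 1L) names(nz)[i]
    else paste0(names(nz)[i], "^", nz[i])
  }, character(1)), collapse = " * ")
}

# -- configuration ------------------------------------------------------------

#' Configuration of the ligand/site binding network
#'
#' Describes which ligands exist, which DNA sites they may occupy, and which
#' solution dimers may form. The default reproduces the PPARgamma:RXRalpha /
#' PPRE system: a two-site DNA element whose left site accepts either ligand
#' and whose right site accepts only the second ligand (RXRalpha, which binds
#' the two hexameric half-sites with equal affinity), RXRalpha
#' homodimerization, and PPARgamma:RXRalpha heterodimerization.
#'
#' @param ligands Character vector of one or two ligand labels. The first
#'   ligand plays the PPARgamma role, the second the RXRalpha role.
#' @param sites Character vector of site labels, length one or two.
#' @param left_accepts Ligands allowed on the first (left) site.
#' @param right_accepts Ligands allowed on the second (right) site. Must not
#'   contain the first ligand (the left site is the only one it can contact).
#' @param heterodimer Logical; may the two ligands dimerize in solution?
#' @param homodimer Character vector of ligands allowed to homodimerize
#'   (default: the second ligand only).
#' @param unit Concentration unit; association constants are per this unit.
#' @return An object of class \code{network_config}.
#' @examples
#' cfg <- network_config()
#' cfg
#' @export
network_config <- function(ligands = c("P", "R"),
                           sites = c("left", "right"),
                           left_accepts = ligands,
                           right_accepts = if (length(ligands) == 2)
                             ligands[2] else character(),
                           heterodimer = length(ligands) == 2,
                           homodimer = if (length(ligands) == 2)
                             ligands[2] else character(),
                           unit = "nM") {
  if (!length(ligands) %in% 1:2 || anyDuplicated(ligands))
    stop("'ligands' must name one or two distinct ligands", call. = FALSE)
  if (!length(sites) %in% 1:2 || anyDuplicated(sites))
    stop("'sites' must name one or two distinct DNA sites", call. = FALSE)
  if (length(sites) == 1 && length(right_accepts))
    stop("config error: a one-site system cannot accept ligands on a ",
         "second site", call. = FALSE)
  if (!all(left_accepts %in% ligands) || !all(right_accepts %in% ligands))
    stop("config error: site acceptance lists unknown ligand", call. = FALSE)
  if (length(ligands) == 2 && ligands[1] %in% right_accepts)
    stop("config error: violated rule 'first ligand may only contact the ",
         "left site' (", ligands[1], " allowed on right site)", call. = FALSE)
  if (heterodimer && length(ligands) != 2)
    stop("config error: heterodimerization needs two ligands", call. = FALSE)
  if (!all(homodimer %in% ligands))
    stop("config error: homodimer lists unknown ligand", call. = FALSE)
  if (length(ligands) == 2 && ligands[1] %in% homodimer)
    stop("config error: violated rule 'only the second ligand may ",
         "homodimerize'", call. = FALSE)
  structure(list(ligands = ligands, sites = sites,
                 left_accepts = left_accepts, right_accepts = right_accepts,
                 heterodimer = isTRUE(heterodimer), homodimer = homodimer,
                 unit = unit),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("Binding network configuration\n")
  cat("  ligands:      ", paste(x$ligands, collapse = ", "), "\n")
  cat("  sites:        ", paste(x$sites, collapse = ", "), "\n")
  cat("  left accepts: ", paste(x$left_accepts, collapse = ", "), "\n")
  if (length(x$sites) == 2)
    cat("  right accepts:", paste(x$right_accepts, collapse = ", "), "\n")
  cat("  heterodimer:  ", x$heterodimer, "\n")
  cat("  homodimer:    ", paste(x$homodimer, collapse = ", "), "\n")
  cat("  unit:         ", x$unit, "\n")
  invisible(x)
}

.ligand_digit <- function(config, ligand) {
  as.character(match(ligand, config$ligands))
}

# -- species + reaction enumeration ------------------------------------------

#' Enumerate the species and elementary reactions of a binding network
#'
#' Builds the full species list of the three-component system (DNA element,
#' two ligands) together with every elementary association step. Under the
#' default configuration this yields the fifteen species of the
#' PPARgamma/RXRalpha/PPRE system: free PPRE (X_0), the free monomers (X_1,
#' X_2), the solution dimers (X_D1, X_D2), the singly and doubly site-bound
#' complexes (X_10, X_20, X_02, X_12, X_22) and the singly-tethered dimers
#' (X_120, X_012, X_022, X_220, X_210), where e.g. X_120 is the
#' heterodimer contacting DNA only through RXRalpha on the left site.
#'
#' Each reaction carries its association constant as an exact monomial in the
#' six primary constants, so thermodynamic cycle closure holds by
#' construction.
#'
#' @param config A \code{\link{network_config}}.
#' @return An object of class \code{reaction_network} with elements
#'   \code{species} (data frame: id, counts of DNA and each ligand, site
#'   occupancy, tethered subunit), \code{formation} (list of overall
#'   formation-constant monomials, free species omitted) and
#'   \code{reactions} (data frame of elementary steps with constant
#'   monomials).
#' @examples
#' net <- build_network()
#' nrow(net$species)   # 15
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  lig <- config$ligands
  two_sites <- length(config$sites) == 2

  # site-binding monomial of a ligand (same for left and right site)
  site_mono <- function(l) {
    if (l == lig[1]) .mono(K_00_10 = 1) else .mono(K_00_02 = 1)
  }
  dimer_mono <- function(a, b) {
    if (a == b) .mono(K_D2 = 1) else .mono(K_D1 = 1)
  }
  ternary_mono <- function(a, b) {    # both sites engaged
    if (a == b) .mono(K_00_22 = 1) else .mono(K_00_12 = 1)
  }

  sp <- list()
  frm <- list()
  add_species <- function(id, n_dna, counts, left = "", right = "",
                          tether = "", role, mono = NULL) {
    sp[[length(sp) + 1L]] <<- data.frame(
      id = id, n_dna = n_dna,
      n_l1 = counts[1], n_l2 = if (length(lig) == 2) counts[2] else 0L,
      site_left = left, site_right = right, tethered_subunit = tether,
      role = role, stringsAsFactors = FALSE)
    if (!is.null(mono)) frm[[id]] <<- mono
  }
  cts <- function(...) {  # ligand counts from labels
    v <- integer(2); for (l in c(...)) v[match(l, lig)] <- v[match(l, lig)] + 1L
    v
  }

  add_species("X_0", 1L, cts(), role = "free_dna")
  for (l in lig) add_species(paste0("X_", .ligand_digit(config, l)), 0L,
                             cts(l), role = "monomer")
  dimers <- list()
  if (config$heterodimer) dimers <- c(dimers, list(c(lig[1], lig[2])))
  for (l in config$homodimer) dimers <- c(dimers, list(c(l, l)))
  dimer_id <- function(pair) if (pair[1] != pair[2]) "X_D1" else "X_D2"
  for (pair in dimers)
    add_species(dimer_id(pair), 0L, cts(pair[1], pair[2]), role = "dimer",
                mono = dimer_mono(pair[1], pair[2]))

  # site-bound complexes: every non-empty assignment of sites to ligands
  left_opts <- c("", config$left_accepts)
  right_opts <- if (two_sites) c("", config$right_accepts) else ""
  dg <- function(l) if (l == "") "0" else .ligand_digit(config, l)
  for (L in left_opts) for (Rr in right_opts) {
    if (L == "" && Rr == "") next
    id <- paste0("X_", dg(L), if (two_sites) dg(Rr) else "0")
    mono <- if (L != "" && Rr != "") ternary_mono(L, Rr)
            else site_mono(c(L, Rr)[c(L, Rr) != ""])
    add_species(id, 1L, cts(c(L, Rr)[c(L, Rr) != ""]), left = L, right = Rr,
                role = if (L != "" && Rr != "") "ternary" else "bound",
                mono = mono)
  }

  # singly-tethered dimers: dimer contacts one site via one subunit, the
  # other site stays free; the DNA contact uses the monomer constant
  if (two_sites) {
    for (pair in dimers) {
      for (side in c("left", "right")) {
        accepts <- if (side == "left") config$left_accepts else
          config$right_accepts
        for (contact in unique(pair)) {
          if (!contact %in% accepts) next
          other <- if (pair[1] == contact) pair[2] else pair[1]
          # canonical labels: dangling subunit's digit precedes the
          # DNA-contacting subunit's digit (X_120, X_012, X_210, ...)
          id <- if (side == "left")
            paste0("X_", dg(other), dg(contact), "0")
          else paste0("X_0", dg(other), dg(contact))
          add_species(id, 1L, cts(pair[1], pair[2]),
                      left = if (side == "left") contact else "",
                      right = if (side == "right") contact else "",
                      tether = contact, role = "tethered",
                      mono = .mono_mul(dimer_mono(pair[1], pair[2]),
                                       site_mono(contact)))
        }
      }
    }
  }

  species <- do.call(rbind, sp)
  canon <- c("X_0", "X_1", "X_2", "X_D1", "X_D2", "X_10", "X_20", "X_02",
             "X_12", "X_22", "X_120", "X_012", "X_022", "X_220", "X_210")
  ord <- order(match(species$id, canon, nomatch = length(canon) + 1L))
  species <- species[ord, , drop = FALSE]
  rownames(species) <- species$id

  # elementary reactions; constants follow from overall formation monomials
  rx <- list()
  rx_monos <- list()
  add_rx <- function(r1, r2, product, kind) {
    g <- function(id) if (id %in% names(frm)) frm[[id]] else .mono()
    m <- .mono_div(g(product), .mono_mul(g(r1), if (is.na(r2)) .mono()
                                         else g(r2)))
    rx[[length(rx) + 1L]] <<- data.frame(
      label = paste0(r1, if (!is.na(r2)) paste0(" + ", r2) else "",
                     " -> ", product),
      reactant1 = r1, reactant2 = r2, product = product, kind = kind,
      constant = .mono_format(m), stringsAsFactors = FALSE)
    rx_monos[[length(rx_monos) + 1L]] <<- m
    invisible(NULL)
  }
  lid <- function(l) paste0("X_", .ligand_digit(config, l))

  for (pair in dimers)
    add_rx(lid(pair[1]), lid(pair[2]), dimer_id(pair), "dimerization")
  bound <- species[species$role %in% c("bound", "ternary"), , drop = FALSE]
  for (i in seq_len(nrow(bound))) {
    s <- bound[i, ]
    occ <- c(s$site_left, s$site_right)
    n_occ <- sum(occ != "")
    if (n_occ == 1) {
      add_rx("X_0", lid(occ[occ != ""]), s$id, "monomer_binding")
    } else {
      # second monomer joins each singly-bound precursor
      for (drop_site in 1:2) {
        pre <- occ; pre[drop_site] <- ""
        pre_id <- paste0("X_", dg(pre[1]), dg(pre[2]))
        if (pre_id %in% species$id)
          add_rx(pre_id, lid(occ[drop_site]), s$id, "site_engagement")
      }
    }
  }
  teth <- species[species$role == "tethered", , drop = FALSE]
  for (i in seq_len(nrow(teth))) {
    s <- teth[i, ]
    contact <- s$tethered_subunit
    # recover the non-contacting subunit from the composition
    rem <- c(s$n_l1, s$n_l2)[seq_along(lig)]
    rem[match(contact, lig)] <- rem[match(contact, lig)] - 1L
    other <- lig[which(rem > 0)]
    d_id <- if (contact == other) "X_D2" else "X_D1"
    # dimer binds DNA via the contacting subunit
    add_rx("X_0", d_id, s$id, "dimer_binding")
    # free monomer dimerizes onto the DNA-bound contacting subunit
    side_occ <- if (s$site_left != "") c(s$site_left, "") else c("", s$site_right)
    pre_id <- paste0("X_", dg(side_occ[1]), dg(side_occ[2]))
    if (pre_id %in% species$id)
      add_rx(pre_id, lid(other), s$id, "tether_formation")
    # intramolecular engagement of the dangling subunit, if its site allows
    free_side <- if (s$site_left == "") "left" else "right"
    accepts <- if (free_side == "left") config$left_accepts else
      config$right_accepts
    if (other %in% accepts) {
      tgt_occ <- c(s$site_left, s$site_right)
      tgt_occ[if (free_side == "left") 1 else 2] <- other
      tgt_id <- paste0("X_", dg(tgt_occ[1]), dg(tgt_occ[2]))
      if (tgt_id %in% species$id)
        add_rx(s$id, NA_character_, tgt_id, "engagement")
    }
  }

  reactions <- do.call(rbind, rx)
  rownames(reactions) <- NULL

  structure(list(config = config, species = species, formation = frm,
                 reactions = reactions, reaction_monomials = rx_monos),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", nrow(x$species), "species,",
      nrow(x$reactions), "elementary reactions\n")
  cat("Species:", paste(x$species$id, collapse = ", "), "\n")
  invisible(x)
}

#' Count the free parameters of a constant network
#'
#' With a set of primary constants fixed (by default the two monomer-DNA
#' binding constants and the two solution dimerization constants, which are
#' measured in independent experiments), every remaining elementary constant
#' is a monomial in the primaries, so the number of independent parameters is
#' the number of unfixed primaries that actually appear in the network.
#' For the default heterodimer network this is exactly two: the overall
#' ternary constants \code{K_00_12} and \code{K_00_22}.
#'
#' @param network A \code{\link{build_network}} result.
#' @param fixed Character vector of primary constants treated as known.
#' @return Integer count of free parameters.
#' @export
free_parameter_count <- function(network,
                                 fixed = c("K_00_10", "K_00_02",
                                           "K_D1", "K_D2")) {
  stopifnot(inherits(network, "reaction_network"))
  used <- Reduce(`+`, lapply(c(network$formation,
                               network$reaction_monomials),
                             function(m) as.integer(m != 0L)),
                 accumulate = FALSE)
  used <- setNames(used > 0, .primary_constants)
  sum(used & !(names(used) %in% fixed))
}
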