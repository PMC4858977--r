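# -- equilibrium solver -------------------------------------------------------

# Internal: exponent matrix (species x components) and overall formation
# constants, reduced to components with non-zero totals.
.solver_setup <- function(network, constants) {
  sp <- network$species
  N <- cbind(dna = sp$n_dna, l1 = sp$n_l1, l2 = sp$n_l2)
  rownames(N) <- sp$id
  G <- rep(1, nrow(sp))
  names(G) <- sp$id
  G[names(constants$formation)] <- constants$formation
  list(N = N, G = G)
}

# Internal: free concentrations -> full species vector
.species_conc <- function(x, N, G) {
  # x on the scale of free concentrations; zeros propagate correctly
  G * exp(N %*% log(pmax(x, .Machine$double.xmin)))[, 1] *
    (apply(N, 1, function(n) all(x[n > 0] > 0)))
}

# Internal Newton core on the reduced system: free concentrations of the
# active components only. Nl: species x active exponents, Gl: formation
# constants, Ta: positive totals. Returns list(xa, conc, resid, iter).
.newton_solve <- function(Nl, Gl, Ta, xa = NULL, tol = 1e-12,
                          max_iter = 200L) {
  k <- length(Ta)
  lGl <- log(Gl)
  conc_of <- function(xa) exp(lGl + (Nl %*% log(xa))[, 1])
  if (is.null(xa)) {
    # Gauss-Seidel warm start: closed-form update per component (species
    # are at most linear in DNA/ligand1 and at most quadratic in ligand2)
    xa <- Ta
    deg1 <- lapply(seq_len(k), function(j) Nl[, j] == 1)
    deg2 <- lapply(seq_len(k), function(j) Nl[, j] == 2)
    for (sweep in 1:60) {
      x_old <- xa
      for (j in seq_len(k)) {
        other <- exp(lGl + (Nl[, -j, drop = FALSE] %*%
                              log(xa[-j]))[, 1])
        if (!any(deg2[[j]])) {
          xa[j] <- Ta[j] / sum(other[deg1[[j]]])
        } else {
          A <- sum(other[deg1[[j]]]); B <- sum(other[deg2[[j]]])
          xa[j] <- if (B > 0) 2 * Ta[j] / (A + sqrt(A^2 + 8 * B * Ta[j]))
                   else Ta[j] / A
        }
      }
      if (max(abs(xa - x_old) / xa) < 1e-3) break
    }
  }
  conc <- conc_of(xa)
  Fv <- log(as.numeric(crossprod(Nl, conc)) / Ta)
  it <- 0L
  while (max(abs(Fv)) > tol && it < max_iter) {
    it <- it + 1L
    J <- crossprod(Nl, Nl * conc) / as.numeric(crossprod(Nl, conc))
    step <- tryCatch(solve(J, Fv), error = function(e) Fv / diag(J))
    step <- pmin(pmax(step, -20), 20)
    lam <- 1
    improved <- FALSE
    for (half in 1:12) {
      xa_new <- xa * exp(-lam * step)
      conc_new <- conc_of(xa_new)
      F_new <- log(as.numeric(crossprod(Nl, conc_new)) / Ta)
      if (all(is.finite(F_new)) && max(abs(F_new)) < max(abs(Fv))) {
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break   # stagnated; caller retries from a cold start
    xa <- xa_new; conc <- conc_new; Fv <- F_new
  }
  list(xa = xa, conc = conc, resid = max(abs(Fv)), iter = it,
       converged = max(abs(Fv)) <= tol)
}

#' Solve the binding network at equilibrium
#'
#' Finds non-negative species concentrations satisfying every equilibrium
#' relation and the mass balance of each component. The solver works on the
#' free concentrations of DNA and the two ligands (all complexes follow from
#' the equilibrium relations), warm-starts with closed-form Gauss-Seidel
#' sweeps, polishes with damped Newton iterations in log-concentration space
#' (which guarantees positivity), and falls back to long-time kinetic
#' integration if Newton fails to converge.
#'
#' @param network A \code{\link{build_network}} result.
#' @param constants A cycle-closed constant set from
#'   \code{\link{close_cycles}}.
#' @param totals A \code{\link{totals_vector}} (or named numeric with
#'   elements \code{total_dna}, \code{total_p}, \code{total_r}).
#' @param tol Relative tolerance on the component mass balances.
#' @param max_iter Maximum Newton iterations.
#' @return A data frame of class \code{species_state} with columns
#'   \code{species_id}, \code{concentration} plus composition counts;
#'   attributes carry the totals, balance and equilibrium-relation residuals
#'   and a convergence flag.
#' @examples
#' net <- build_network()
#' cc  <- close_cycles(net, equilibrium_constants(0.1, 0.2, 0.05, 0.02,
#'                                                K_00_12 = 2, K_00_22 = 0.008))
#' st  <- solve_equilibrium(net, cc, totals_vector(10, 5, 20))
#' sum(st$concentration[st$n_dna > 0])  # = 10 (DNA balance)
#' @export
solve_equilibrium <- function(network, constants, totals,
                              tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(constants, "closed_constants"))
  totals <- unclass(totals)
  if (is.null(names(totals))) names(totals) <- c("total_dna", "total_p",
                                                 "total_r")
  stopifnot(all(c("total_dna", "total_p", "total_r") %in% names(totals)))
  T_ <- pmax(totals[c("total_dna", "total_p", "total_r")], 0)
  su <- .solver_setup(network, constants)
  N <- su$N; G <- su$G
  active <- which(T_ > 0)

  x <- c(0, 0, 0)
  converged <- TRUE
  resid <- 0
  if (length(active)) {
    # drop species containing an absent component
    live <- vapply(seq_len(nrow(N)), function(s)
      all(N[s, setdiff(1:3, active)] == 0), logical(1))
    sol <- .newton_solve(N[live, active, drop = FALSE], G[live], T_[active],
                         tol = tol, max_iter = max_iter)
    converged <- sol$converged
    resid <- sol$resid
    x[active] <- sol$xa
  }

  if (!converged) {
    ks <- simulate_kinetics(network, constants, totals)
    if (!attr(ks, "converged"))
      stop("equilibrium solver failed to converge; max balance residual ",
           signif(resid, 3), call. = FALSE)
    return(ks)
  }

  conc <- .species_conc(x, N, G)
  .make_state(network, constants, T_, conc, converged = TRUE)
}

# Internal: package a concentration vector as a species_state with residuals
.make_state <- function(network, constants, totals, conc, converged) {
  sp <- network$species
  st <- data.frame(species_id = sp$id, concentration = as.numeric(conc),
                   n_dna = sp$n_dna, n_l1 = sp$n_l1, n_l2 = sp$n_l2,
                   stringsAsFactors = FALSE)
  rownames(st) <- st$species_id
  bal <- c(total_dna = sum(st$concentration * st$n_dna),
           total_p = sum(st$concentration * st$n_l1),
           total_r = sum(st$concentration * st$n_l2))
  bal_res <- abs(bal - totals) / pmax(totals, .Machine$double.eps)
  rx <- constants$derived
  eq_res <- vapply(seq_len(nrow(rx)), function(i) {
    r1 <- st[rx$reactant1[i], "concentration"]
    r2 <- if (is.na(rx$reactant2[i])) 1 else st[rx$reactant2[i], "concentration"]
    lhs <- rx$value[i] * r1 * r2
    rhs <- st[rx$product[i], "concentration"]
    abs(lhs - rhs) / max(abs(lhs), abs(rhs), .Machine$double.xmin)
  }, numeric(1))
  structure(st, totals = totals, balance_residuals = bal_res,
            equilibrium_residuals = setNames(eq_res, rx$label),
            ligands = network$config$ligands, converged = converged,
            unit = constants$unit, class = c("species_state", "data.frame"))
}

#' Steady state by mass-action kinetic integration
#'
#' Integrates the mass-action ODE system of the elementary reactions until
#' every reaction is at equilibrium. Forward and reverse rates keep the
#' ratio given by each reaction's association constant (only ratios matter
#' at the fixed point); each reaction's absolute rates are scaled so its
#' characteristic forward rate is of order one at the concentration scale
#' of the problem, which tames the stiffness of extreme constant draws
#' without moving the steady state. Integration proceeds over expanding
#' time checkpoints and stops once the largest relative reaction
#' disequilibrium falls below \code{steady_tol}. This is an independent
#' route to the same equilibrium point as \code{\link{solve_equilibrium}}
#' and serves as its cross-validation oracle; it is much slower.
#'
#' @inheritParams solve_equilibrium
#' @param horizon Integration end time, in units where the fastest scaled
#'   reaction relaxes in about one time unit.
#' @param steady_tol Threshold on the largest relative disequilibrium
#'   |K x reactants - product| / max(...) across reactions (species below
#'   1e-14 of the concentration scale are exempt) below which the state is
#'   deemed steady.
#' @return A \code{species_state}; attribute \code{converged} is FALSE if
#'   the horizon was reached while reactions were still out of equilibrium.
#' @export
simulate_kinetics <- function(network, constants, totals, horizon = 1e10,
                              steady_tol = 3e-11) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(constants, "closed_constants"))
  totals <- unclass(totals)
  if (is.null(names(totals)))
    names(totals) <- c("total_dna", "total_p", "total_r")
  T_ <- pmax(totals[c("total_dna", "total_p", "total_r")], 0)
  sp <- network$species
  rx <- constants$derived
  n_sp <- nrow(sp)
  i1 <- match(rx$reactant1, sp$id)
  i2 <- match(rx$reactant2, sp$id)
  ip <- match(rx$product, sp$id)
  scale <- max(T_, 1)
  # per-reaction rate scaling: preserves kf/kr = K, evens out timescales
  cj <- 1 / pmax(1, rx$value * ifelse(is.na(i2), 1, scale))
  kf <- rx$value * cj
  kr <- cj

  # stoichiometry: reactants consumed (twice for A + A), product formed
  S <- matrix(0, n_sp, nrow(rx))
  for (r in seq_len(nrow(rx))) {
    S[i1[r], r] <- S[i1[r], r] - 1
    if (!is.na(i2[r])) S[i2[r], r] <- S[i2[r], r] - 1
    S[ip[r], r] <- S[ip[r], r] + 1
  }

  y0 <- numeric(n_sp)
  y0[sp$id == "X_0"] <- T_["total_dna"]
  y0[sp$role == "monomer" & sp$n_l1 == 1] <- T_["total_p"]
  y0[sp$role == "monomer" & sp$n_l2 == 1] <- T_["total_r"]

  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- kf * y[i1] * ifelse(is.na(i2), 1, y[i2]) - kr * y[ip]
    list(as.numeric(S %*% v))
  }
  diseq <- function(y) {
    lhs <- rx$value * y[i1] * ifelse(is.na(i2), 1, y[i2])
    rhs <- y[ip]
    mx <- pmax(lhs, rhs)
    max(ifelse(mx < 1e-14 * scale, 0, abs(lhs - rhs) / pmax(mx, 1e-300)))
  }

  checkpoints <- 10 ^ seq(-2, log10(horizon), by = 0.5)
  y_end <- y0
  t_now <- 0
  steady <- diseq(y_end) < steady_tol
  for (t_next in checkpoints) {
    if (steady) break
    sol <- suppressWarnings(
      deSolve::ode(y = y_end, times = c(t_now, t_next), func = deriv,
                   parms = NULL, method = "lsoda", rtol = 1e-10,
                   atol = 1e-13 * scale, maxsteps = 5e5))
    last <- sol[nrow(sol), ]
    if (!any(is.na(last))) {   # keep partial progress on step-limit returns
      y_end <- pmax(as.numeric(last[-1]), 0)
      t_now <- t_next
    }
    steady <- diseq(y_end) < steady_tol
  }
  .make_state(network, constants, T_, y_end, converged = steady)
}

#' Fraction of DNA bound to a given ligand
#'
#' The observable of the surface-tethered fluorescence readout: the fraction
#' of the DNA element engaged in complexes that contain the immobilized
#' ligand. For the PPARgamma readout this is
#' ([X_10] + [X_12] + [X_120] + [X_012] + [X_210]) / total DNA, i.e. every
#' DNA-containing species whose composition includes PPARgamma; the
#' RXRalpha readout is defined symmetrically.
#'
#' @param state A \code{species_state}.
#' @param readout \code{"P"} (first ligand) or \code{"R"} (second ligand),
#'   or one of the configured ligand labels.
#' @return The bound fraction, in [0, 1].
#' @export
observable_fraction <- function(state, readout = c("P", "R")) {
  stopifnot(inherits(state, "species_state"))
  ligands <- attr(state, "ligands")
  readout <- match.arg(readout[1], unique(c("P", "R", ligands)))
  idx <- if (readout %in% c("P", ligands[1])) "n_l1" else "n_l2"
  total_dna <- attr(state, "totals")[["total_dna"]]
  if (total_dna <= 0)
    stop("bound fraction undefined: total DNA is zero", call. = FALSE)
  sum(state$concentration[state$n_dna > 0 & state[[idx]] > 0]) / total_dna
}

#' @export
print.species_state <- function(x, ...) {
  cat("Species state (", attr(x, "unit"), "); converged: ",
      attr(x, "converged"), "\n", sep = "")
  print.data.frame(x[, c("species_id", "concentration")], row.names = FALSE)
  cat("max balance residual:", signif(max(attr(x, "balance_residuals")), 3),
      "\n")
  invisible(x)
}

# Internal: bound-to-ligand DNA concentration across a titration design.
# Warm-starts each point from the previous solution; used by the heterodimer
# fit and the dataset simulator where thousands of equilibria are solved.
.bound_dna_batch <- function(network, constants, design,
                             readout = "P", tol = 1e-12) {
  su <- .solver_setup(network, constants)
  N <- su$N; G <- su$G
  ligands <- network$config$ligands
  idx <- if (readout %in% c("P", ligands[1])) "l1" else "l2"
  mask <- N[, "dna"] > 0 & N[, idx] > 0

  Tm <- cbind(pmax(design$total_dna_nM, 0), pmax(design$total_p_nM, 0),
              pmax(design$total_r_nM, 0))
  out <- numeric(nrow(Tm))
  pat_key <- apply(Tm > 0, 1, paste, collapse = "")
  for (pat in unique(pat_key)) {
    rows <- which(pat_key == pat)
    active <- which(Tm[rows[1], ] > 0)
    if (!length(active)) { out[rows] <- 0; next }
    live <- vapply(seq_len(nrow(N)), function(s)
      all(N[s, setdiff(1:3, active)] == 0), logical(1))
    Nl <- N[live, active, drop = FALSE]
    Gl <- G[live]
    mask_l <- mask[live]
    xa <- NULL
    Ta_prev <- NULL
    for (i in rows) {
      Ta <- Tm[i, active]
      start <- if (!is.null(xa)) pmin(xa * Ta / Ta_prev, Ta) else NULL
      sol <- .newton_solve(Nl, Gl, Ta, xa = start, tol = tol)
      if (!sol$converged)   # retry cold
        sol <- .newton_solve(Nl, Gl, Ta, tol = tol, max_iter = 500L)
      if (!sol$converged)
        stop("equilibrium solve failed at design point ", i,
             " (residual ", signif(sol$resid, 3), ")", call. = FALSE)
      out[i] <- sum(sol$conc[mask_l])
      xa <- sol$xa
      Ta_prev <- Ta
    }
  }
  out
}
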