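# -- binding-curve fitting ----------------------------------------------------

# Closed-form bound complex concentration of the one-site equilibrium
# P + D <-> PD at association constant K (the positive root of the
# quadratic in [PD]).
.one_site_bound <- function(K, total_p, total_d) {
  s <- total_p + total_d + 1 / K
  as.numeric((s - sqrt(s^2 - 4 * total_p * total_d)) / 2)
}

# Profile out the signal gain: for fixed bound-concentration predictions b,
# the least-squares gain is sum(s*b)/sum(b^2).
.profile_gain <- function(signal, bound) {
  sb2 <- sum(bound^2)
  if (sb2 == 0) 0 else sum(signal * bound) / sb2
}

.check_curve <- function(curve, min_conc = 3L) {
  stopifnot(is.data.frame(curve),
            all(c("total_dna_nM", "signal") %in% names(curve)))
  n_conc <- length(unique(curve$total_dna_nM))
  if (n_conc < min_conc)
    stop("insufficient data: need >= ", min_conc,
         " distinct DNA concentrations, got ", n_conc, call. = FALSE)
  if (any(curve$total_dna_nM < 0) || any(!is.finite(curve$signal)))
    stop("concentrations must be non-negative and signals finite",
         call. = FALSE)
  invisible(curve)
}

#' Fit a one-site binding constant to a titration curve
#'
#' Fits the single-parameter non-linear binding function: at each titration
#' point the bound complex follows the exact quadratic solution of the
#' one-site equilibrium P + D = PD at fixed total protein, and the observed
#' fluorescence is a free instrument gain times the bound concentration.
#' The association constant minimizing the unweighted chi-square (= residual
#' sum of squares) is located by a log-spaced multi-start grid followed by
#' local refinement; the lowest-chi-square start wins. The standard
#' deviation of the constant comes from the Jacobian-based curvature at the
#' optimum.
#'
#' @param curve Data frame of observations with columns \code{total_dna_nM}
#'   and \code{signal} (the \code{\link{read_binding_table}} schema).
#' @param fixed_protein_total Total protein concentration (nM), > 0.
#' @param k_range Log10 range of the association constant grid (1/nM).
#' @param n_starts Number of log-spaced grid points (16 per decade over
#'   the default eight-decade range).
#' @return A \code{binding_fit} with the estimated constant \code{K}, the
#'   signal gain, chi2/RSS, residuals, parameter standard deviation and a
#'   convergence flag.
#' @examples
#' # noiseless curve generated at K = 0.05/nM, gain 1.7, P_total = 10 nM
#' d <- data.frame(total_dna_nM = c(1, 2, 5, 10, 20, 50, 100, 200))
#' s <- 10 + d$total_dna_nM + 1 / 0.05
#' d$signal <- 1.7 * (s - sqrt(s^2 - 4 * 10 * d$total_dna_nM)) / 2
#' fit_one_site(d, fixed_protein_total = 10)
#' @export
fit_one_site <- function(curve, fixed_protein_total,
                         k_range = c(-4, 4), n_starts = 129L) {
  .check_curve(curve)
  if (!is.numeric(fixed_protein_total) || fixed_protein_total <= 0)
    stop("fixed_protein_total must be positive", call. = FALSE)
  d <- curve$total_dna_nM
  s <- curve$signal
  boundary <- all(s == 0)

  obj <- function(logK) {
    b <- .one_site_bound(exp(logK), fixed_protein_total, d)
    g <- .profile_gain(s, b)
    sum((s - g * b)^2)
  }
  grid <- log(10 ^ seq(k_range[1], k_range[2], length.out = n_starts))
  rss_grid <- vapply(grid, obj, numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, c(lo, hi), tol = 1e-12)
  logK <- opt$minimum
  K <- exp(logK)
  b <- .one_site_bound(K, fixed_protein_total, d)
  gain <- .profile_gain(s, b)
  resid <- s - gain * b
  rss <- sum(resid^2)

  # curvature-based sigma: full Jacobian in (K, gain)
  h <- max(K * 1e-6, 1e-12)
  dbdK <- (.one_site_bound(K + h, fixed_protein_total, d) -
             .one_site_bound(K - h, fixed_protein_total, d)) / (2 * h)
  J <- cbind(K = gain * dbdK, gain = b)
  sigma_K <- .curvature_sigma(J, rss, length(s))["K"]

  .binding_fit(parameters = c(K = K), gain = gain, chi2 = rss, rss = rss,
               residuals = resid, sigma = c(K = unname(sigma_K)),
               converged = !boundary, n = length(s),
               flags = if (boundary) "all-zero signal: boundary fit"
                       else character())
}

# sigma of parameters from the residual-based curvature at the optimum
.curvature_sigma <- function(J, rss, n) {
  p <- ncol(J)
  dof <- max(n - p, 1)
  s2 <- rss / dof
  cv <- tryCatch(s2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, p, p))
  setNames(sqrt(pmax(diag(cv), 0)), colnames(J))
}

.binding_fit <- function(parameters, gain, chi2, rss, residuals, sigma,
                         converged, n, flags = character()) {
  structure(list(parameters = parameters, gain = gain, chi2 = chi2,
                 rss = rss, residuals = residuals, sigma = sigma,
                 converged = converged, n = n, flags = flags),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Binding fit (n = ", x$n, ")\n", sep = "")
  for (p in names(x$parameters))
    cat(sprintf("  %-10s %.6g  (sigma %.3g)\n", p, x$parameters[p],
                if (p %in% names(x$sigma)) x$sigma[p] else NA))
  cat(sprintf("  gain       %.6g\n  RSS        %.6g\n", x$gain, x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the two ternary constants of the heterodimer model
#'
#' Estimates the overall ternary association constants \code{K_00_12} and
#' \code{K_00_22} from a titration dataset, given the four binary constants
#' measured in independent experiments. At each design point the full
#' species network is solved at equilibrium and the predicted signal is
#' gain x (DNA bound to the immobilized ligand); the two constants minimize
#' the unweighted least squares against the observed signals. Multi-start
#' over a log-spaced grid, Nelder-Mead refinement of the best starts.
#'
#' @param dataset Data frame with columns \code{total_dna_nM},
#'   \code{total_p_nM}, \code{total_r_nM}, \code{signal}.
#' @param fixed An \code{\link{equilibrium_constants}} set with
#'   \code{K_00_10}, \code{K_00_02}, \code{K_D1}, \code{K_D2} set (the
#'   ternary entries are ignored).
#' @param network Optional prebuilt \code{\link{build_network}} result.
#' @param readout Immobilized ligand whose bound-DNA signal was measured.
#' @param start_grid Log10 grid of multi-start values for both constants.
#' @param n_refine Number of best starts refined by Nelder-Mead.
#' @param solver_tol Relative mass-balance tolerance of the inner
#'   equilibrium solves (looser than the standalone solver default; the
#'   objective only needs accuracy well below the measurement noise).
#' @return A \code{binding_fit} with parameters \code{K_00_12},
#'   \code{K_00_22}, the gain, RSS and per-parameter sigma.
#' @export
fit_heterodimer <- function(dataset, fixed, network = build_network(),
                            readout = "P",
                            start_grid = seq(-4, 4, by = 2),
                            n_refine = 3L, solver_tol = 1e-10) {
  .check_curve(dataset)
  stopifnot(inherits(fixed, "equilibrium_constants"),
            all(c("total_p_nM", "total_r_nM") %in% names(dataset)))
  binaries <- fixed$values[c("K_00_10", "K_00_02", "K_D1", "K_D2")]
  if (any(is.na(binaries)) || any(binaries <= 0))
    stop("the four binary constants must be set and positive", call. = FALSE)

  s <- dataset$signal
  design <- dataset[, c("total_dna_nM", "total_p_nM", "total_r_nM")]
  failed_starts <- character()

  predict_bound <- function(logk) {
    ks <- equilibrium_constants(binaries[["K_00_10"]], binaries[["K_00_02"]],
                                binaries[["K_D1"]], binaries[["K_D2"]],
                                K_00_12 = exp(logk[1]),
                                K_00_22 = exp(logk[2]), unit = fixed$unit)
    cc <- close_cycles(network, ks)
    .bound_dna_batch(network, cc, design, readout = readout,
                     tol = solver_tol)
  }
  obj <- function(logk) {
    b <- tryCatch(predict_bound(logk), error = function(e) NULL)
    if (is.null(b)) {
      failed_starts <<- c(failed_starts, paste(signif(exp(logk), 3),
                                               collapse = "/"))
      return(Inf)
    }
    g <- .profile_gain(s, b)
    sum((s - g * b)^2)
  }

  starts <- as.matrix(expand.grid(log(10 ^ start_grid), log(10 ^ start_grid)))
  rss0 <- apply(starts, 1, obj)
  if (all(!is.finite(rss0)))
    stop("heterodimer fit failed: no start converged", call. = FALSE)
  best <- order(rss0)[seq_len(min(n_refine, sum(is.finite(rss0))))]
  fits <- lapply(best, function(i)
    optim(starts[i, ], obj, method = "Nelder-Mead",
          control = list(maxit = 250, reltol = 1e-10)))
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  # polish around the winner
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-13))

  logk <- fit$par
  b <- predict_bound(logk)
  gain <- .profile_gain(s, b)
  resid <- s - gain * b
  rss <- sum(resid^2)

  # numeric Jacobian wrt (K12, K22, gain) for curvature sigma
  J <- matrix(0, length(s), 3,
              dimnames = list(NULL, c("K_00_12", "K_00_22", "gain")))
  for (j in 1:2) {
    h <- 1e-5
    lp <- logk; lp[j] <- lp[j] + h
    lm_ <- logk; lm_[j] <- lm_[j] - h
    # derivative wrt K on natural scale: d(gain*b)/dK = gain * db/dlogK / K
    J[, j] <- gain * (predict_bound(lp) - predict_bound(lm_)) /
      (2 * h) / exp(logk[j])
  }
  J[, 3] <- b
  sig <- .curvature_sigma(J, rss, length(s))

  .binding_fit(parameters = c(K_00_12 = unname(exp(logk[1])),
                              K_00_22 = unname(exp(logk[2]))),
               gain = gain, chi2 = rss, rss = rss, residuals = resid,
               sigma = sig[1:2], converged = fit$convergence == 0,
               n = length(s),
               flags = if (length(failed_starts))
                 paste("non-convergent starts discarded:",
                       paste(unique(failed_starts), collapse = ", "))
               else character())
}

#' Relative DNA affinity as a linear slope
#'
#' In the sub-saturation (linear) regime of the binding curve, the relative
#' affinity of a factor for a sequence is the slope of protein-normalized
#' bound signal versus total input DNA. The line is intercept-free by
#' default (washed, DNA-free units show no signal); set
#' \code{intercept = TRUE} for an ordinary free-intercept regression.
#'
#' @param points Data frame with columns \code{total_dna_nM} and
#'   \code{signal} (signal already normalized by protein level upstream).
#' @param intercept Fit a free intercept instead of forcing zero.
#' @return The least-squares slope (signal units per nM).
#' @export
relative_affinity <- function(points, intercept = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("total_dna_nM", "signal") %in% names(points)))
  x <- points$total_dna_nM
  y <- points$signal
  if (length(unique(x)) < 2)
    stop("insufficient data: need >= 2 distinct DNA concentrations",
         call. = FALSE)
  if (intercept) unname(coef(lm(y ~ x))[2])
  else sum(x * y) / sum(x * x)
}
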