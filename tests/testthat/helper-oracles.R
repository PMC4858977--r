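# Independent oracles used across the suite. Each re-derives its quantity
# by a route separate from the package implementation (closed forms, brute
# enumeration, exhaustive grids).

# Closed-form bound complex of P + D <-> PD (positive quadratic root)
oracle_quadratic_bound <- function(K, total_p, total_d) {
  s <- total_p + total_d + 1 / K
  (s - sqrt(s^2 - 4 * total_p * total_d)) / 2
}

# Exhaustive grid search for the one-site constant: profile the gain and
# scan RSS over a dense log grid
oracle_grid_search_K <- function(curve, total_p, n_grid = 1e4,
                                 lo = 1e-4, hi = 1e4) {
  grid <- 10 ^ seq(log10(lo), log10(hi), length.out = n_grid)
  rss <- vapply(grid, function(K) {
    b <- oracle_quadratic_bound(K, total_p, curve$total_dna_nM)
    g <- sum(curve$signal * b) / sum(b^2)
    sum((curve$signal - g * b)^2)
  }, numeric(1))
  list(K = grid[which.min(rss)],
       grid_step = log10(hi / lo) / (n_grid - 1))
}

# Best-fit Hill exponent of a one-dimensional binding curve
oracle_hill_exponent <- function(d, y) {
  obj <- function(p) {
    h <- exp(p[3])
    pred <- exp(p[1]) * d^h / (exp(p[2])^h + d^h)
    sum((y - pred)^2)
  }
  best <- NULL
  for (k0 in log(c(5, 20, 100, 400)))
    for (h0 in log(c(0.8, 1, 1.5, 2.5))) {
      o <- optim(c(log(max(y)), k0, h0), obj,
                 control = list(maxit = 3000, reltol = 1e-13))
      if (is.null(best) || o$value < best$value) best <- o
    }
  exp(best$par[3])
}

# O(n^2) pairwise AUC with half-credit ties
oracle_auc_pairwise <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# Brute-force best-window log-odds scan over both strands; reverse strand
# handled by explicitly reverse-complementing the sequence (a different
# route than the implementation's matrix flip)
oracle_scan <- function(P, sequence, pseudocount = 1e-3) {
  bases <- c("A", "C", "G", "T")
  bg <- attr(P, "background")
  S <- log2((unclass(P) + pseudocount) /
              matrix(bg + pseudocount, nrow(P), 4, byrow = TRUE))
  score_window <- function(win) {
    ch <- strsplit(win, "")[[1]]
    sum(vapply(seq_along(ch), function(i) {
      j <- match(ch[i], bases)
      if (is.na(j)) 0 else S[i, j]
    }, numeric(1)))
  }
  revcomp <- function(s)
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  L <- nrow(P)
  n <- nchar(sequence)
  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    for (start in seq_len(n - L + 1)) {
      win <- substr(sequence, start, start + L - 1)
      sc <- score_window(if (strand == "+") win else revcomp(win))
      if (sc > best$score)
        best <- list(score = sc, start = start, strand = strand)
    }
  }
  best
}

# Evaluate a pathway product by explicit lookup in the derived table
oracle_path_product <- function(closed, labels) {
  prod(vapply(labels, function(l) {
    closed$derived$value[match(l, closed$derived$label)]
  }, numeric(1)))
}

# A random positive primary constant set
random_constants <- function(lo = 1e-3, hi = 1e3) {
  v <- 10 ^ runif(6, log10(lo), log10(hi))
  equilibrium_constants(v[1], v[2], v[3], v[4], v[5], v[6])
}

default_network <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network()
    net
  }
})

# Near-deterministic probability matrix around a consensus sequence
sharp_pssm <- function(consensus, p = 0.97) {
  L <- nchar(consensus)
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p) / 3, L, 4)
  m[cbind(seq_len(L), idx)] <- p
  probability_matrix(m, tol = 1e-9)
}
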