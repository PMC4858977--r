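# -- binding specificity models ----------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

#' Position probability matrix
#'
#' A per-position base probability matrix (PSSM in probability form) with a
#' background distribution. Rows are motif positions, columns A, C, G, T.
#'
#' @param x Numeric matrix (L x 4) of probabilities; columns are taken in
#'   A, C, G, T order (named columns are reordered).
#' @param background Background base frequencies, default uniform.
#' @param name Optional motif name.
#' @param tol Tolerance on row sums (printed matrices are only given to
#'   three decimals, hence the permissive default).
#' @return A matrix of class \code{prob_matrix}.
#' @export
probability_matrix <- function(x, background = rep(0.25, 4), name = NULL,
                               tol = 0.01) {
  x <- as.matrix(x)
  if (ncol(x) != 4) stop("need 4 columns (A, C, G, T)", call. = FALSE)
  if (!is.null(colnames(x)) && all(DNA_BASES %in% colnames(x)))
    x <- x[, DNA_BASES, drop = FALSE]
  colnames(x) <- DNA_BASES
  if (any(x < 0) || any(!is.finite(x)))
    stop("probabilities must be finite and non-negative", call. = FALSE)
  if (any(abs(rowSums(x) - 1) > tol))
    stop("rows must sum to 1 within ", tol, call. = FALSE)
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  structure(x, background = setNames(background, DNA_BASES),
            motif_name = name, class = c("prob_matrix", "matrix", "array"))
}

#' @export
print.prob_matrix <- function(x, ...) {
  nm <- attr(x, "motif_name")
  cat("Probability matrix", if (!is.null(nm)) paste0("'", nm, "'"),
      "- length", nrow(x), "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Convert binding energies or constants to a probability matrix
#'
#' Under the independence assumption (each nucleotide contributes to
#' binding independently), the per-position probability of base b is the
#' Boltzmann weight of its binding energy: p(i,b) = exp(-ddG(i,b)/RT)
#' normalized across the four bases, which for association constants is
#' equivalent to p(i,b) = K(i,b) / sum_b' K(i,b').
#'
#' @param x Either an L x 4 matrix of ddG values (kcal/mol; the reference
#'   base has 0 at its own position) or, with \code{type = "constants"},
#'   an L x 4 matrix of association constants of the single-substitution
#'   variants carrying each base.
#' @param RT Thermal energy (kcal/mol) used for the Boltzmann weights.
#' @param type \code{"energy"} or \code{"constants"}.
#' @param ... Passed to \code{\link{probability_matrix}}.
#' @return A \code{prob_matrix}.
#' @examples
#' K <- rbind(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' energy_to_pssm(K, type = "constants")   # first row 0.1 0.2 0.3 0.4
#' @export
energy_to_pssm <- function(x, RT = 0.593, type = c("energy", "constants"),
                           ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != 4) stop("need 4 columns (A, C, G, T)", call. = FALSE)
  if (any(is.na(x)))
    stop("incomplete matrix: a value is required for every base at every ",
         "position", call. = FALSE)
  w <- if (type == "energy") exp(-x / RT) else x
  if (any(w < 0)) stop("constants must be non-negative", call. = FALSE)
  p <- w / rowSums(w)
  probability_matrix(p, tol = 1e-9, ...)
}

#' Recover relative binding energies from a probability matrix
#'
#' The inverse of \code{\link{energy_to_pssm}}: ddG(i,b) =
#' -RT log(p(i,b) / p(i, ref_b)) relative to the most probable (consensus)
#' base of each position, so the consensus entry is 0.
#'
#' @param P A \code{prob_matrix}.
#' @param RT Thermal energy (kcal/mol).
#' @return An L x 4 matrix of ddG values (kcal/mol).
#' @export
pssm_to_energy <- function(P, RT = 0.593) {
  stopifnot(inherits(P, "prob_matrix"))
  p <- unclass(P)
  ref <- apply(p, 1, max)
  -RT * log(p / ref)
}

#' Per-position information content
#'
#' IC_i = 2 + sum_b p(i,b) log2 p(i,b) bits against a uniform background,
#' with 0 log 0 taken as 0; between 0 (uniform) and 2 (deterministic).
#'
#' @param P A \code{prob_matrix}.
#' @return Numeric vector of bits, one per position.
#' @export
information_content <- function(P) {
  stopifnot(inherits(P, "prob_matrix"))
  p <- unclass(P)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  2 + rowSums(plogp)
}

# log-odds score matrix: pseudocount added to both motif and background
# probabilities before the log so that a uniform motif scores exactly zero
.score_matrix <- function(P, pseudocount = 1e-3) {
  bg <- attr(P, "background")
  log2((unclass(P) + pseudocount) /
         matrix(bg + pseudocount, nrow(P), 4, byrow = TRUE))
}

.revcomp_matrix <- function(M) {
  M <- M[rev(seq_len(nrow(M))), rev(seq_len(ncol(M))), drop = FALSE]
  colnames(M) <- DNA_BASES
  M
}

#' Scan a sequence with a probability matrix
#'
#' Slides the motif over every window of the sequence on both strands and
#' returns the best log-odds score, position and strand. Scoring is
#' sum_i log2(p(i, base) / background) with a small pseudocount added
#' before the log; non-ACGT characters score as background (contribution
#' zero). Ties are broken towards the leftmost position, forward strand
#' first.
#'
#' @param P A \code{prob_matrix}.
#' @param sequence A single character string or
#'   \code{\link[Biostrings]{DNAString}}.
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @param pseudocount Pseudocount added to probabilities before the log.
#' @return A list: \code{score} (bits), \code{start} (1-based offset of the
#'   best window), \code{strand} ("+" or "-"), \code{n_windows}.
#' @examples
#' P <- probability_matrix(diag(4)[c(1, 2, 3), ] * 0.97 + 0.0075)
#' scan_pssm(P, "TTTTACGTTTT")$start   # finds ACG at offset 5
#' @export
scan_pssm <- function(P, sequence, both_strands = TRUE, pseudocount = 1e-3) {
  stopifnot(inherits(P, "prob_matrix"))
  sequence <- toupper(as.character(sequence))
  L <- nrow(P)
  n <- nchar(sequence)
  if (n < L)
    stop("scan error: sequence (", n, " nt) shorter than motif (", L,
         " nt)", call. = FALSE)
  base_idx <- match(strsplit(sequence, "")[[1]], DNA_BASES)  # NA = ambiguous
  n_win <- n - L + 1

  window_scores <- function(S) {
    # column s of scores: contributions of motif position i at window w
    sc <- numeric(n_win)
    for (i in seq_len(L)) {
      b <- base_idx[i:(i + n_win - 1)]
      contrib <- ifelse(is.na(b), 0, S[i, ifelse(is.na(b), 1L, b)])
      sc <- sc + contrib
    }
    sc
  }
  S_fwd <- .score_matrix(P, pseudocount)
  scores <- data.frame(start = seq_len(n_win), strand = "+",
                       score = window_scores(S_fwd))
  if (both_strands) {
    S_rev <- .revcomp_matrix(S_fwd)
    scores <- rbind(scores,
                    data.frame(start = seq_len(n_win), strand = "-",
                               score = window_scores(S_rev)))
  }
  ord <- order(-scores$score, scores$strand != "+", scores$start)
  best <- scores[ord[1], ]
  list(score = best$score, start = best$start, strand = best$strand,
       n_windows = n_win)
}

#' Best motif score per region
#'
#' @param P A \code{prob_matrix}.
#' @param regions Character vector or \code{DNAStringSet} of sequences.
#' @param ... Passed to \code{\link{scan_pssm}}.
#' @return Numeric vector of best log-odds scores, named by region.
#' @export
score_regions <- function(P, regions, ...) {
  seqs <- as.character(regions)
  vapply(seqs, function(s) scan_pssm(P, s, ...)$score, numeric(1))
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen positive region outscores a
#' randomly chosen negative one, with ties counted one half — the
#' Wilcoxon-Mann-Whitney statistic, equal to the area under the ROC curve.
#'
#' @param positive_scores,negative_scores Non-empty numeric score vectors.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(3, 4, 5), c(1, 2, 3))   # 8.5/9
#' @export
roc_auc <- function(positive_scores, negative_scores) {
  if (!length(positive_scores) || !length(negative_scores))
    stop("evaluation error: both score sets must be non-empty",
         call. = FALSE)
  stopifnot(all(is.finite(positive_scores)), all(is.finite(negative_scores)))
  n_pos <- length(positive_scores)
  n_neg <- length(negative_scores)
  r <- rank(c(positive_scores, negative_scores), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Count regions predicted bound at a score threshold
#'
#' @param scores Per-region best log-odds scores.
#' @param threshold Numeric threshold; if NULL, derived from \code{pssm} by
#'   the named rule.
#' @param pssm Motif used to derive the default threshold.
#' @param rule Threshold rule; \code{"fraction_of_max"} takes
#'   \code{fraction} times the motif's maximum attainable log-odds score.
#' @param fraction Fraction for the default rule.
#' @return A list: \code{n_predicted}, \code{n_total}, \code{threshold},
#'   \code{rule}.
#' @export
predict_occurrence <- function(scores, threshold = NULL, pssm = NULL,
                               rule = "fraction_of_max", fraction = 0.6) {
  if (is.null(threshold)) {
    if (is.null(pssm))
      stop("either a threshold or a pssm (for the default rule) is needed",
           call. = FALSE)
    max_score <- sum(apply(.score_matrix(pssm), 1, max))
    threshold <- fraction * max_score
    rule <- sprintf("%s (%.2g x max score %.4g)", rule, fraction, max_score)
  } else rule <- "explicit threshold"
  list(n_predicted = sum(scores >= threshold), n_total = length(scores),
       threshold = threshold, rule = rule)
}

# -- MEME minimal motif I/O ---------------------------------------------------

#' Read motifs from a MEME minimal format file
#'
#' @param path Path to a MEME minimal format motif file.
#' @return Named list of \code{prob_matrix} objects.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^MEME version", lines)))
    stop("parse error: not a MEME minimal file (missing version line): ",
         path, call. = FALSE)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) && bg_i[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    if (length(tok) == 8) bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  motif_i <- grep("^MOTIF", lines)
  out <- list()
  for (m in motif_i) {
    name <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[m:length(lines)])[1] + m - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    vals <- lapply(seq_along(rows), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]]))
      if (length(v) != 4 || any(is.na(v)))
        stop("parse error at line ", h + i, " of ", path,
             ": expected 4 numeric fields", call. = FALSE)
      v
    })
    out[[name]] <- probability_matrix(do.call(rbind, vals), background = bg,
                                      name = name)
  }
  if (!length(out)) stop("parse error: no MOTIF entries in ", path,
                         call. = FALSE)
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs A \code{prob_matrix} or named list of them.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "prob_matrix")) {
    nm <- attr(motifs, "motif_name")
    motifs <- setNames(list(motifs), if (is.null(nm)) "motif" else nm)
  }
  bg <- attr(motifs[[1]], "background")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +",
               "", "Background letter frequencies (from uniform background):",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3],
                       bg[4]), ""), con)
  for (nm in names(motifs)) {
    P <- motifs[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(P)), con)
    writeLines(apply(unclass(P), 1, function(r)
      paste(sprintf("%.6f", r), collapse = "\t")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Build a probability matrix from per-variant binding constants
#'
#' Maps the fitted constants of a single-substitution library onto an
#' L x 4 constants matrix (each position's reference base takes the
#' reference sequence's constant) and Boltzmann-normalizes it into a
#' probability matrix. Variant identifiers must follow the
#' \code{\link{substitution_library}} convention
#' \code{<name>_p<position><ref>><base>} / \code{<name>_ref}.
#'
#' @param values Named numeric vector of association constants, one per
#'   library sequence.
#' @param reference Reference sequence (ACGT string) the library was built
#'   from.
#' @param name Motif name for the result.
#' @return A \code{prob_matrix} of length \code{nchar(reference)}.
#' @export
constants_to_pssm <- function(values, reference, name = NULL) {
  reference <- toupper(as.character(reference))
  chars <- strsplit(reference, "")[[1]]
  L <- length(chars)
  ref_id <- grep("_ref$", names(values), value = TRUE)
  if (length(ref_id) != 1)
    stop("expected exactly one '<name>_ref' entry, found ",
         length(ref_id), call. = FALSE)
  K <- matrix(NA_real_, L, 4, dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(L)) K[i, chars[i]] <- values[[ref_id]]
  m <- regmatches(names(values), regexec("_p(\\d+)([ACGT])>([ACGT])$",
                                         names(values)))
  for (j in seq_along(values)) {
    if (length(m[[j]]) != 4) next
    i <- as.integer(m[[j]][2])
    if (i < 1 || i > L || chars[i] != m[[j]][3])
      stop("variant id ", names(values)[j],
           " does not match the reference sequence", call. = FALSE)
    K[i, m[[j]][4]] <- values[[j]]
  }
  if (any(is.na(K)))
    stop("incomplete matrix: missing variants for ",
         sum(is.na(K)), " position/base combinations", call. = FALSE)
  energy_to_pssm(K, type = "constants", name = name)
}
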