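# -- tabular and sequence I/O -------------------------------------------------

.binding_cols <- c("sequence_id", "total_dna_nM", "total_p_nM",
                   "total_r_nM", "signal", "replicate")

#' Read a binding table
#'
#' Tab- or comma-separated table with header columns \code{sequence_id},
#' \code{total_dna_nM}, \code{total_p_nM}, \code{total_r_nM},
#' \code{signal}, \code{replicate}.
#'
#' @param path Input file.
#' @return Data frame in the binding-table schema.
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first) && !grepl("\t", first)) "," else "\t"
  df <- tryCatch(read.delim(path, sep = sep, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  missing <- setdiff(.binding_cols, names(df))
  if (length(missing))
    stop("parse error in ", path, " (line 1): missing columns ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(df))
    stop("parse error in ", path, ": table has no data rows", call. = FALSE)
  for (cl in setdiff(.binding_cols, c("sequence_id", "replicate"))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad))
      stop("parse error in ", path, " (line ", bad[1] + 1L,
           "): non-numeric value in column ", cl, call. = FALSE)
    df[[cl]] <- as.numeric(df[[cl]])
  }
  df
}

#' Write a binding table
#'
#' @param df Data frame in the binding-table schema.
#' @param path Output file (TSV).
#' @return Invisibly, the path.
#' @export
write_binding_table <- function(df, path) {
  stopifnot(all(.binding_cols %in% names(df)))
  write.table(df[, .binding_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a solved species state as TSV
#'
#' @param state A \code{species_state}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_species_state <- function(state, path) {
  stopifnot(inherits(state, "species_state"))
  write.table(data.frame(species_id = state$species_id,
                         concentration = state$concentration),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write equilibrium constants as YAML
#'
#' Human-readable serialization carrying the unit field.
#'
#' @param constants An \code{\link{equilibrium_constants}} set.
#' @param path File path.
#' @return \code{write_constants_yaml}: the path, invisibly;
#'   \code{read_constants_yaml}: an \code{equilibrium_constants} set.
#' @export
write_constants_yaml <- function(constants, path) {
  stopifnot(inherits(constants, "equilibrium_constants"))
  v <- as.list(constants$values)
  v <- lapply(v, function(x) if (is.na(x)) NULL else x)
  yaml::write_yaml(c(list(unit = constants$unit), v), path)
  invisible(path)
}

#' @rdname write_constants_yaml
#' @export
read_constants_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("unit", .primary_constants)
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("config error: unknown keys in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  g <- function(k) if (is.null(y[[k]])) NA_real_ else as.numeric(y[[k]])
  equilibrium_constants(g("K_00_10"), g("K_00_02"), g("K_D1"), g("K_D2"),
                        g("K_00_12"), g("K_00_22"),
                        unit = if (is.null(y$unit)) "nM" else y$unit)
}

#' Write a region set as FASTA (and optionally BED labels)
#'
#' The BED companion uses 0-based half-open coordinates over each region's
#' own sequence and scores the label (1 positive, 0 negative).
#'
#' @param regions A \code{region_set}.
#' @param fasta Output FASTA path.
#' @param bed Optional output BED path for the labels.
#' @return Invisibly, the FASTA path.
#' @export
write_regions <- function(regions, fasta, bed = NULL) {
  stopifnot(inherits(regions, "region_set"))
  Biostrings::writeXStringSet(regions$sequences, fasta)
  if (!is.null(bed)) {
    df <- data.frame(chrom = names(regions$sequences),
                     start = 0L,
                     end = Biostrings::width(regions$sequences),
                     name = names(regions$sequences),
                     score = regions$labels,
                     strand = "+")
    write.table(df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(fasta)
}

#' Read a labelled region set from FASTA + BED
#'
#' @param fasta FASTA of region sequences.
#' @param bed BED file whose score column holds the 0/1 labels (as written
#'   by \code{\link{write_regions}}).
#' @return A \code{region_set}.
#' @export
read_regions <- function(fasta, bed) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  df <- tryCatch(read.delim(bed, header = FALSE, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("parse error in ", bed, ": ", conditionMessage(e),
                        call. = FALSE))
  if (ncol(df) < 5)
    stop("parse error in ", bed, ": expected >= 5 BED columns",
         call. = FALSE)
  labels <- setNames(as.integer(df[[5]]), df[[4]])
  if (!all(names(seqs) %in% names(labels)))
    stop("region labels missing for some FASTA entries", call. = FALSE)
  structure(list(sequences = seqs, labels = unname(labels[names(seqs)]),
                 region_length = max(Biostrings::width(seqs)),
                 fidelity = NA_real_, provenance = "user-supplied"),
            class = "region_set")
}

#' Export fit results as TSV
#'
#' @param fits Named list of \code{binding_fit} objects (names = sequence
#'   ids) or a single fit.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_fit_results <- function(fits, path) {
  if (inherits(fits, "binding_fit")) fits <- list(fit = fits)
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(sequence_id = id,
               parameter = names(f$parameters),
               estimate = unname(f$parameters),
               sigma = unname(f$sigma[names(f$parameters)]),
               gain = f$gain, rss = f$rss, n = f$n,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Typed configuration bundle for scripted runs; serializable to YAML and
#' back. Unknown keys are rejected on read.
#'
#' @param unit Concentration unit.
#' @param RT Thermal energy (kcal/mol).
#' @param solver_tol Equilibrium solver tolerance.
#' @param n_starts One-site multi-start grid size.
#' @param noise_cv,noise_floor Generator noise model.
#' @param gain Generator signal gain.
#' @param threshold_fraction Fraction-of-max rule for peak prediction.
#' @param seed Default seed.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(unit = "nM", RT = 0.593, solver_tol = 1e-12,
                            n_starts = 129L, noise_cv = 0.01,
                            noise_floor = 0.005, gain = 2,
                            threshold_fraction = 0.6, seed = 17L) {
  structure(list(unit = unit, RT = RT, solver_tol = solver_tol,
                 n_starts = as.integer(n_starts), noise_cv = noise_cv,
                 noise_floor = noise_floor, gain = gain,
                 threshold_fraction = threshold_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config = pipeline_config(), path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A \code{pipeline_config} (write) — read returns one.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("config error: unknown keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, y)
}

#' Serialize a network configuration to YAML
#'
#' @param config A \code{\link{network_config}}.
#' @param path File path.
#' @return \code{write_network_config}: the path, invisibly;
#'   \code{read_network_config}: a \code{network_config}.
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(network_config))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("config error: unknown keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  y[c("left_accepts", "right_accepts", "homodimer")] <-
    lapply(y[c("left_accepts", "right_accepts", "homodimer")],
           function(v) if (is.null(v)) character() else as.character(v))
  do.call(network_config, y)
}
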