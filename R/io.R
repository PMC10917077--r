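#' Save / load a protein feature table
#'
#' Text format: header `#protein-emb d=<int>` then
#' `protein_id<TAB>v1...v_d` rows at full precision.
#'
#' @param proteins Numeric matrix n x d with protein rownames.
#' @param path File path.
#' @return `save_protein_table`: `path` invisibly; `load_protein_table`: the
#'   matrix.
#' @export
save_protein_table <- function(proteins, path) {
  stopifnot(is.matrix(proteins), !is.null(rownames(proteins)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#protein-emb d=%d", ncol(proteins)), con)
  writeLines(vapply(seq_len(nrow(proteins)), function(i) {
    paste(c(rownames(proteins)[[i]], sprintf("%.17g", proteins[i, ])),
          collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

#' @rdname save_protein_table
#' @export
load_protein_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hd <- regmatches(lines[[1]], regexec("^#protein-emb d=(\\d+)$", lines[[1]]))[[1]]
  if (length(hd) != 2L) {
    stop_po2go("missing or malformed #protein-emb header", "po2go_format_error")
  }
  d <- as.integer(hd[[2]])
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) != d + 1L)) {
    stop_po2go("row width does not match d", "po2go_format_error")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  P <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(d)))
  if (d == 1L) P <- matrix(P, ncol = 1L)
  rownames(P) <- ids
  P
}

#' Write / read prediction scores as a long TSV
#'
#' Columns `protein_id`, `term_id`, `score`; rows below `min_score` are
#' dropped to bound file size.
#'
#' @param scores Matrix proteins x terms.
#' @param path File path.
#' @param min_score Score floor for emitted rows.
#' @return `write_predictions`: `path` invisibly; `read_predictions`: a
#'   scores matrix (absent cells are 0).
#' @export
write_predictions <- function(scores, path, min_score = 0.01) {
  keep <- which(scores >= min_score, arr.ind = TRUE)
  df <- data.frame(
    protein_id = rownames(scores)[keep[, 1]],
    term_id = colnames(scores)[keep[, 2]],
    score = sprintf("%.17g", scores[keep])
  )
  df <- df[order(df$protein_id, df$term_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @param proteins,terms Row/column universes for the reconstructed matrix;
#'   default those present in the file.
#' @export
read_predictions <- function(path, proteins = NULL, terms = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  proteins <- proteins %||% unique(df$protein_id)
  terms <- terms %||% unique(df$term_id)
  out <- matrix(0, length(proteins), length(terms),
                dimnames = list(proteins, terms))
  out[cbind(match(df$protein_id, proteins), match(df$term_id, terms))] <- df$score
  out
}

#' Write a pair benchmark and its annotations to TSV
#' @param benchmark A [generate_pair_benchmark()] result.
#' @param pairs_path,annotations_path Output paths.
#' @return `pairs_path`, invisibly.
#' @export
write_pair_benchmark <- function(benchmark, pairs_path, annotations_path) {
  utils::write.table(as.data.frame(benchmark)[, c("protein_a", "protein_b", "target")],
                     pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sets <- attr(benchmark, "annotations")
  ann <- data.frame(
    protein_id = rep(names(sets), lengths(sets)),
    term_id = unlist(sets, use.names = FALSE)
  )
  utils::write.table(ann, annotations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(pairs_path)
}
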