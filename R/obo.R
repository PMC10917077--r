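#' Parse an OBO 1.2/1.4 ontology
#'
#' Reads `[Term]` stanzas and keeps only the two transitive relationship types
#' through which GO annotations safely propagate: `is_a:` and
#' `relationship: part_of`. Every other relationship type (`regulates`,
#' `occurs_in`, ...) is dropped. Obsolete terms are retained as records but
#' carry no edges and are never indexed or embedded. `alt_id:` accessions are
#' recorded and resolve to their primary id.
#'
#' @param source Path to an OBO file, or a character vector of OBO lines.
#' @return An [ontology_dag] object.
#' @examples
#' obo <- c("[Term]", "id: A:1", "name: root", "namespace: d1",
#'          "", "[Term]", "id: A:2", "name: leaf", "namespace: d1",
#'          "is_a: A:1 ! root")
#' dag <- parse_obo(obo)
#' dag$terms
#' @export
parse_obo <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
  lines <- sub("\\s+$", "", lines)

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$id)) {
      stop_po2go(sprintf("[Term] stanza starting at line %d has no id:", cur$start),
                 "po2go_parse_error")
    }
    terms[[length(terms) + 1L]] <<- cur
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "[Term]") {
      flush(cur)
      in_term <- TRUE
      cur <- list(start = i, id = NULL, name = NA_character_,
                  namespace = NA_character_, obsolete = FALSE,
                  alt_ids = character(), parents = character(),
                  relations = character())
      next
    }
    if (grepl("^\\[", ln)) { # [Typedef] or other stanza: close any open term
      flush(cur)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || ln == "" || grepl("^!", ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 0L) {
      stop_po2go(sprintf("malformed OBO line %d: '%s'", i, ln), "po2go_parse_error")
    }
    key <- m[[2]]
    val <- sub("\\s*!.*$", "", m[[3]]) # strip trailing comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "alt_id") cur$alt_ids <- c(cur$alt_ids, val)
    else if (key == "is_a") {
      cur$parents <- c(cur$parents, val)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2L && parts[[1]] == "part_of") {
        cur$parents <- c(cur$parents, parts[[2]])
        cur$relations <- c(cur$relations, "part_of")
      } # other relationship types dropped
    }
  }
  flush(cur)
  if (length(terms) == 0L) stop_po2go("no [Term] stanzas found", "po2go_parse_error")

  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_po2go(sprintf("duplicated term id: %s", ids[duplicated(ids)][1]),
               "po2go_parse_error")
  }
  ns <- vapply(terms, `[[`, character(1), "namespace")
  ns[is.na(ns)] <- "default"
  term_tbl <- tibble::tibble(
    term_id = ids,
    name = vapply(terms, `[[`, character(1), "name"),
    domain = ns,
    obsolete = vapply(terms, `[[`, logical(1), "obsolete")
  )
  alt <- unlist(lapply(terms, function(tt) {
    if (length(tt$alt_ids)) stats::setNames(rep(tt$id, length(tt$alt_ids)), tt$alt_ids)
    else NULL
  }))
  edges <- do.call(rbind, lapply(terms, function(tt) {
    if (tt$obsolete || length(tt$parents) == 0L) return(NULL)
    data.frame(child = tt$id, parent = tt$parents, relation = tt$relations,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(edges$parent), ids)
  if (length(unknown)) {
    stop_po2go(sprintf("edge references unknown term: %s", unknown[1]),
               "po2go_parse_error")
  }
  ontology_dag(term_tbl, tibble::as_tibble(edges), alt_ids = alt)
}

#' Write an ontology to OBO format
#'
#' Inverse of [parse_obo()] for the subset of OBO this package models
#' (is_a / part_of edges, namespaces, obsolete flags).
#'
#' @param dag An [ontology_dag].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "po2go_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  edges <- dag$edges
  for (i in seq_len(nrow(dag$terms))) {
    tid <- dag$terms$term_id[[i]]
    out <- c("[Term]",
             paste0("id: ", tid),
             paste0("name: ", dag$terms$name[[i]]),
             paste0("namespace: ", dag$terms$domain[[i]]))
    if (dag$terms$obsolete[[i]]) out <- c(out, "is_obsolete: true")
    e <- edges[edges$child == tid, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[[j]] == "is_a") {
        paste0("is_a: ", e$parent[[j]])
      } else {
        paste0("relationship: part_of ", e$parent[[j]])
      })
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Read protein-to-term annotation pairs
#'
#' Accepts GAF 2.x (tab-separated, comment lines starting with `!`; protein id
#' from column 2, term id from column 5, evidence code from column 7) or a
#' headerless two-column TSV `protein_id<TAB>term_id`.
#'
#' @param path Input file.
#' @param format `"auto"`, `"gaf"` or `"tsv"`.
#' @param evidence Optional character vector of GAF evidence codes to keep
#'   (e.g. `c("EXP","IDA")`); `NULL` keeps everything.
#' @return A tibble with columns `protein_id`, `term_id`.
#' @export
read_annotation_pairs <- function(path, format = c("auto", "gaf", "tsv"),
                                  evidence = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(body) == 0L) {
    return(tibble::tibble(protein_id = character(), term_id = character()))
  }
  ncol1 <- length(strsplit(body[[1]], "\t", fixed = TRUE)[[1]])
  if (format == "auto") format <- if (ncol1 >= 15L) "gaf" else "tsv"
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (format == "gaf") {
    ann <- tibble::tibble(
      protein_id = vapply(fields, `[[`, character(1), 2L),
      term_id = vapply(fields, `[[`, character(1), 5L),
      evidence = vapply(fields, `[[`, character(1), 7L)
    )
    if (!is.null(evidence)) ann <- ann[ann$evidence %in% evidence, ]
    ann$evidence <- NULL
  } else {
    bad <- which(vapply(fields, length, integer(1)) < 2L)
    if (length(bad)) {
      stop_po2go(sprintf("annotation TSV line %d has fewer than 2 columns", bad[1]),
                 "po2go_parse_error")
    }
    ann <- tibble::tibble(
      protein_id = vapply(fields, `[[`, character(1), 1L),
      term_id = vapply(fields, `[[`, character(1), 2L)
    )
  }
  dplyr::distinct(ann)
}
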