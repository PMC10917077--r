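#' Construct an ontology DAG
#'
#' The central container: a directed acyclic graph of ontology terms whose
#' edges point child -> parent and are labelled `is_a` or `part_of`. Each
#' namespace ("domain", e.g. BPO/MFO/CCO) has exactly one root — the term
#' with no outgoing edge — and every other non-obsolete term must reach it.
#'
#' @param terms A data frame with columns `term_id`, `name`, `domain`,
#'   `obsolete` (`name`/`obsolete` optional).
#' @param edges A data frame with columns `child`, `parent`, `relation`
#'   (relation in `is_a`/`part_of`).
#' @param alt_ids Optional named character vector mapping alternate ids to
#'   primary term ids.
#' @return An object of class `po2go_dag` with elements `terms` (tibble),
#'   `edges` (tibble), `roots` (named by domain), `graph` (igraph over
#'   non-obsolete terms) and `alt_ids`.
#' @export
ontology_dag <- function(terms, edges, alt_ids = NULL) {
  terms <- tibble::as_tibble(terms)
  if (!"name" %in% names(terms)) terms$name <- terms$term_id
  if (!"obsolete" %in% names(terms)) terms$obsolete <- FALSE
  if (!"domain" %in% names(terms)) terms$domain <- "default"
  stopifnot(all(c("term_id", "domain") %in% names(terms)))
  if (anyDuplicated(terms$term_id)) {
    stop_po2go("term_id must be unique within an ontology", "po2go_structure_error")
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
    if (!all(edges$relation %in% c("is_a", "part_of"))) {
      stop_po2go("edge labels must be is_a or part_of", "po2go_structure_error")
    }
    obs <- terms$term_id[terms$obsolete]
    if (any(edges$child %in% obs | edges$parent %in% obs)) {
      stop_po2go("obsolete terms may not carry edges", "po2go_structure_error")
    }
  }
  active <- terms[!terms$obsolete, ]
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = active$term_id, domain = active$domain)
  )
  if (!igraph::is_dag(g)) {
    stop_po2go("edge set contains a cycle", "po2go_structure_error")
  }
  # roots: per domain, the unique term with no outgoing (child->parent) edge
  outdeg <- igraph::degree(g, mode = "out")
  roots <- character()
  for (dom in unique(active$domain)) {
    in_dom <- active$term_id[active$domain == dom]
    r <- in_dom[outdeg[in_dom] == 0L]
    if (length(r) != 1L) {
      stop_po2go(sprintf(
        "domain '%s' must have exactly one root (found %d rootless terms)",
        dom, length(r)), "po2go_structure_error")
    }
    # cross-domain edges would let a term escape its namespace
    cross <- edges$child %in% in_dom &
      !(edges$parent %in% in_dom)
    if (any(cross)) {
      stop_po2go(sprintf("edge crosses domains: %s -> %s",
                         edges$child[cross][1], edges$parent[cross][1]),
                 "po2go_structure_error")
    }
    roots[[dom]] <- r
  }
  structure(
    list(terms = terms, edges = edges, roots = roots, graph = g,
         alt_ids = alt_ids %||% stats::setNames(character(), character())),
    class = "po2go_dag"
  )
}

#' @export
print.po2go_dag <- function(x, ...) {
  cat(sprintf("<po2go_dag> %d terms (%d obsolete), %d edges, %d domain(s): %s\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges),
              length(x$roots), paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

#' Non-obsolete term identifiers
#' @param dag An [ontology_dag].
#' @return Character vector of active (non-obsolete) term ids.
#' @export
active_terms <- function(dag) {
  dag$terms$term_id[!dag$terms$obsolete]
}

#' Resolve term ids against an ontology
#'
#' Maps alternate ids to their primary id and errors on unknown ids.
#' @param dag An [ontology_dag].
#' @param ids Character vector of term ids.
#' @return Character vector of primary ids.
#' @export
resolve_term_ids <- function(dag, ids) {
  ids <- as.character(ids)
  hit_alt <- ids %in% names(dag$alt_ids)
  ids[hit_alt] <- dag$alt_ids[ids[hit_alt]]
  unknown <- setdiff(ids, dag$terms$term_id)
  if (length(unknown)) {
    stop_po2go(sprintf("unknown term id: %s", unknown[1]), "po2go_lookup_error")
  }
  ids
}

check_active <- function(dag, ids) {
  ids <- resolve_term_ids(dag, ids)
  obs <- ids[ids %in% dag$terms$term_id[dag$terms$obsolete]]
  if (length(obs)) {
    stop_po2go(sprintf("term is obsolete: %s", obs[1]), "po2go_lookup_error")
  }
  ids
}

#' Ancestors of a term
#'
#' Transitive closure over child -> parent edges, excluding the term itself.
#' @param dag An [ontology_dag].
#' @param term A term id.
#' @return Character vector of ancestor term ids.
#' @export
ancestors_of <- function(dag, term) {
  term <- check_active(dag, term)
  anc <- igraph::subcomponent(dag$graph, term, mode = "out")$name
  setdiff(anc, term)
}

#' Descendants of a term
#' @inheritParams ancestors_of
#' @return Character vector of descendant term ids.
#' @export
descendants_of <- function(dag, term) {
  term <- check_active(dag, term)
  dec <- igraph::subcomponent(dag$graph, term, mode = "in")$name
  setdiff(dec, term)
}

#' Shortest reachable path (SRP) between two terms
#'
#' The SRP distance has three regimes. If one term is an ancestor of the other
#' (a directed path exists in either orientation) the pair is *direct* and the
#' length is the minimum edge count of such a path. Otherwise, if the two
#' terms share at least one common ancestor, the pair is *indirect* and the
#' length is the minimum over common ancestors `a` of
#' `dist(t_i -> a) + dist(t_j -> a)`, plus 0.5 — so two siblings score 2.5.
#' Pairs with no common ancestor (typically different domains) are
#' *unreachable* with length `+Inf`. The distance is symmetric, and
#' `srp(t, t)` is defined as length 0, direct.
#'
#' @param dag An [ontology_dag].
#' @param t_i,t_j Term ids (non-obsolete).
#' @return A list with elements `length` (numeric) and `reachability`
#'   (`"direct"`, `"indirect"` or `"unreachable"`).
#' @examples
#' dag <- fig2_fixture()
#' srp(dag, "GO:0043227", "GO:0110165") # direct, length 2
#' @export
srp <- function(dag, t_i, t_j) {
  t_i <- check_active(dag, t_i)
  t_j <- check_active(dag, t_j)
  if (t_i == t_j) return(list(length = 0, reachability = "direct"))
  d <- igraph::distances(dag$graph, v = c(t_i, t_j), mode = "out")
  up_i <- d[1, ]
  up_j <- d[2, ]
  if (is.finite(up_i[[t_j]]) || is.finite(up_j[[t_i]])) {
    return(list(length = min(up_i[[t_j]], up_j[[t_i]]), reachability = "direct"))
  }
  through <- up_i + up_j
  m <- suppressWarnings(min(through))
  if (is.finite(m)) {
    list(length = m + 0.5, reachability = "indirect")
  } else {
    list(length = Inf, reachability = "unreachable")
  }
}

#' All-pairs SRP length matrix
#'
#' Dense m x m matrix of SRP lengths over the active terms: positive integers
#' for direct pairs, `integer + 0.5` for indirect pairs, `Inf` for
#' unreachable pairs and 0 on the diagonal.
#'
#' @param dag An [ontology_dag].
#' @return A symmetric numeric matrix with term-id dimnames.
#' @export
srp_matrix <- function(dag) {
  ids <- active_terms(dag)
  D <- igraph::distances(dag$graph, v = ids, to = ids, mode = "out")
  D <- D[ids, ids, drop = FALSE]
  direct <- pmin(D, t(D))
  m <- length(ids)
  indirect <- matrix(Inf, m, m)
  for (k in seq_len(m)) {
    dk <- D[, k]
    fin <- which(is.finite(dk))
    if (length(fin) < 2L) next
    indirect[fin, fin] <- pmin(indirect[fin, fin], outer(dk[fin], dk[fin], "+"))
  }
  out <- direct
  use_ind <- !is.finite(direct) & is.finite(indirect)
  out[use_ind] <- indirect[use_ind] + 0.5
  diag(out) <- 0
  dimnames(out) <- list(ids, ids)
  out
}

#' Classify an SRP length
#' @param len Numeric vector of SRP lengths (as from [srp_matrix()]).
#' @return Character vector: `"direct"`, `"indirect"` or `"unreachable"`
#'   (`"direct"` for 0/self).
#' @export
srp_class <- function(len) {
  ifelse(!is.finite(len), "unreachable",
         ifelse(len %% 1 == 0.5, "indirect", "direct"))
}

#' Term depths (longest path to the domain root)
#'
#' Depth of a term is the number of edges on the *longest* child -> parent
#' path from the term to its domain root; roots have depth 0. Longest path
#' (not shortest) so that a term with both a near and a distant route to the
#' root is counted at its most specific position.
#'
#' @param dag An [ontology_dag].
#' @param terms Optional term ids; default all active terms.
#' @return Named integer vector of depths.
#' @export
term_depths <- function(dag, terms = NULL) {
  ids <- active_terms(dag)
  g <- dag$graph
  # process parents before children: reverse topological order of child->parent
  topo <- igraph::topo_sort(g, mode = "in")$name # roots first
  depth <- stats::setNames(rep(0L, length(ids)), ids)
  adj <- igraph::adjacent_vertices(g, topo, mode = "out")
  for (i in seq_along(topo)) {
    v <- topo[[i]]
    ps <- adj[[i]]$name
    if (length(ps)) depth[[v]] <- max(depth[ps]) + 1L
  }
  if (is.null(terms)) depth[ids] else depth[check_active(dag, terms)]
}

#' Depth of a single term
#' @inheritParams ancestors_of
#' @return Non-negative integer depth.
#' @export
term_depth <- function(dag, term) {
  unname(term_depths(dag, term))
}

#' Build a binary annotation matrix from protein/term pairs
#'
#' @param pairs Data frame with columns `protein_id`, `term_id`.
#' @param dag An [ontology_dag]; term ids are resolved against it.
#' @param proteins Optional protein universe (row order); default the
#'   proteins present in `pairs`.
#' @return Binary matrix (0/1) proteins x active terms.
#' @export
annotation_matrix <- function(pairs, dag, proteins = NULL) {
  ids <- active_terms(dag)
  pairs$term_id <- vapply(seq_len(nrow(pairs)), function(i) {
    tryCatch(check_active(dag, pairs$term_id[[i]]),
             po2go_lookup_error = function(e) {
               stop_po2go(sprintf("protein %s: %s", pairs$protein_id[[i]],
                                  conditionMessage(e)), "po2go_lookup_error")
             })
  }, character(1))
  proteins <- proteins %||% unique(pairs$protein_id)
  y <- matrix(0L, length(proteins), length(ids),
              dimnames = list(proteins, ids))
  y[cbind(match(pairs$protein_id, proteins), match(pairs$term_id, ids))] <- 1L
  y
}

#' Propagate annotations by the true path rule
#'
#' A protein annotated with a term is implicitly annotated with every
#' ancestor of that term; this closes a binary annotation matrix under that
#' rule. Idempotent, and the output always contains the input.
#'
#' @param annotations Binary matrix proteins x terms (colnames = term ids),
#'   or a data frame of `protein_id`/`term_id` pairs.
#' @param dag An [ontology_dag].
#' @return Binary matrix proteins x all active terms, true-path closed.
#' @export
propagate_true_path <- function(annotations, dag) {
  if (is.data.frame(annotations)) {
    annotations <- annotation_matrix(annotations, dag)
  }
  ids <- active_terms(dag)
  unknown <- setdiff(colnames(annotations), dag$terms$term_id)
  if (length(unknown)) {
    stop_po2go(sprintf("annotation uses unknown term: %s", unknown[1]),
               "po2go_lookup_error")
  }
  y <- matrix(0L, nrow(annotations), length(ids),
              dimnames = list(rownames(annotations), ids))
  y[, colnames(annotations)] <- as.integer(annotations > 0)
  A <- ancestor_closure_matrix(dag)
  out <- (y %*% A) > 0
  storage.mode(out) <- "integer"
  out
}

# m x m 0/1 matrix: A[t, a] = 1 iff a == t or a is an ancestor of t
ancestor_closure_matrix <- function(dag) {
  ids <- active_terms(dag)
  D <- igraph::distances(dag$graph, v = ids, to = ids, mode = "out")
  A <- ifelse(is.finite(D[ids, ids, drop = FALSE]), 1L, 0L)
  dimnames(A) <- list(ids, ids)
  A
}
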