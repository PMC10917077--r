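#' The worked-example mini ontology
#'
#' A six-term, two-domain fixture reproducing the printed SRP cases: the
#' direct chain GO:0043227 -> GO:0043226 -> GO:0110165 (length 2), the
#' parent-child pair (length 1), the sibling pair GO:0043227 / GO:0043229
#' (length 2.5), the 3-edge indirect pair GO:0043227 / GO:1990900 (length
#' 3.5) and the cross-domain pair GO:0043227 / GO:0044238 (+Inf). The
#' topology around GO:1990900 and GO:0044238 is synthetic (see the shipped
#' `fig2_synthetic.obo`).
#'
#' @return An [ontology_dag].
#' @export
fig2_fixture <- function() {
  parse_obo(system.file("extdata", "fig2_synthetic.obo", package = "po2go",
                        mustWork = TRUE))
}

#' Synthetic DAG specification
#'
#' @param domains Number of domains (namespaces).
#' @param terms_per_domain Terms per domain, including its root.
#' @param max_children Branching bound per parent.
#' @param multi_parent_prob Probability that a term gets a second parent.
#' @param depth_target Maximum depth of any generated term.
#' @param seed Integer seed.
#' @return List of class `po2go_dag_spec`.
#' @export
dag_spec <- function(domains = 3L, terms_per_domain = 100L, max_children = 4L,
                     multi_parent_prob = 0.2, depth_target = 8L, seed = 0L) {
  stopifnot(is_count(domains), is_count(terms_per_domain), is_count(max_children),
            is.numeric(multi_parent_prob), multi_parent_prob >= 0,
            multi_parent_prob < 1, is_count(depth_target))
  if (depth_target > terms_per_domain) {
    stop_po2go("depth_target exceeds terms_per_domain", "po2go_spec_error")
  }
  structure(list(domains = as.integer(domains),
                 terms_per_domain = as.integer(terms_per_domain),
                 max_children = as.integer(max_children),
                 multi_parent_prob = multi_parent_prob,
                 depth_target = as.integer(depth_target),
                 seed = as.integer(seed)),
            class = "po2go_dag_spec")
}

#' Generate a multi-domain synthetic ontology DAG
#'
#' Each domain grows from its root by sequential attachment: every new term
#' picks one parent uniformly among earlier terms of its domain that are
#' below the depth bound and the branching bound, and with
#' `multi_parent_prob` gains a second parent. Edges always point to
#' earlier-created terms, so the result is acyclic and connected by
#' construction; edge labels alternate is_a / part_of deterministically.
#'
#' @param spec A [dag_spec()].
#' @return An [ontology_dag].
#' @export
generate_dag <- function(spec) {
  stopifnot(inherits(spec, "po2go_dag_spec"))
  with_seed(spec$seed, {
    terms <- list()
    edges <- list()
    for (d in seq_len(spec$domains)) {
      dom <- sprintf("D%02d", d)
      ids <- sprintf("SY:%02d%05d", d, seq_len(spec$terms_per_domain))
      depth <- rep(0L, spec$terms_per_domain)
      nkids <- rep(0L, spec$terms_per_domain)
      for (i in seq_len(spec$terms_per_domain)[-1]) {
        elig <- which(depth[seq_len(i - 1L)] < spec$depth_target &
                        nkids[seq_len(i - 1L)] < spec$max_children)
        if (length(elig) == 0L) elig <- seq_len(i - 1L) # relax branching bound
        p1 <- resample(elig, 1L)
        nkids[[p1]] <- nkids[[p1]] + 1L
        depth[[i]] <- depth[[p1]] + 1L
        parents <- p1
        if (runif(1) < spec$multi_parent_prob && i > 2L) {
          others <- setdiff(seq_len(i - 1L), p1)
          if (length(others)) {
            p2 <- resample(others, 1L)
            parents <- c(parents, p2)
            depth[[i]] <- max(depth[[i]], depth[[p2]] + 1L)
          }
        }
        edges[[length(edges) + 1L]] <- data.frame(
          child = ids[[i]], parent = ids[parents],
          relation = ifelse(seq_along(parents) == 1L, "is_a", "part_of"),
          stringsAsFactors = FALSE)
      }
      terms[[d]] <- tibble::tibble(term_id = ids, name = ids, domain = dom,
                                   obsolete = FALSE)
    }
    edge_tbl <- if (length(edges)) do.call(rbind, edges) else
      data.frame(child = character(), parent = character(), relation = character())
    ontology_dag(do.call(rbind, terms), tibble::as_tibble(edge_tbl))
  })
}

#' Annotation generator specification
#'
#' @param n_proteins Number of proteins.
#' @param leaf_bias Depth weighting exponent: direct terms are drawn with
#'   probability proportional to `(1 + depth)^leaf_bias`, so 0 is uniform
#'   and larger values favour deep (specific) terms.
#' @param terms_per_protein Mean number of direct terms per protein
#'   (1 + Poisson(mean - 1)).
#' @param seed Integer seed.
#' @return List of class `po2go_annotation_spec`.
#' @export
annotation_spec <- function(n_proteins = 100L, leaf_bias = 2, terms_per_protein = 3,
                            seed = 0L) {
  stopifnot(is_count(n_proteins), is.numeric(leaf_bias),
            is.numeric(terms_per_protein), terms_per_protein >= 1)
  structure(list(n_proteins = as.integer(n_proteins), leaf_bias = leaf_bias,
                 terms_per_protein = terms_per_protein, seed = as.integer(seed)),
            class = "po2go_annotation_spec")
}

#' Generate true-path-consistent synthetic annotations
#'
#' Each protein draws its direct terms with depth-biased weights, then the
#' matrix is closed under the true path rule, so the output is always a
#' fixed point of [propagate_true_path()].
#'
#' @param dag An [ontology_dag].
#' @param spec An [annotation_spec()].
#' @return Binary annotation matrix proteins x active terms.
#' @export
generate_annotations <- function(dag, spec) {
  stopifnot(inherits(spec, "po2go_annotation_spec"))
  ids <- active_terms(dag)
  depth <- term_depths(dag)[ids]
  wgt <- (1 + depth)^spec$leaf_bias
  with_seed(spec$seed, {
    prots <- sprintf("P%05d", seq_len(spec$n_proteins))
    y <- matrix(0L, spec$n_proteins, length(ids), dimnames = list(prots, ids))
    for (i in seq_len(spec$n_proteins)) {
      n_direct <- 1L + stats::rpois(1, spec$terms_per_protein - 1)
      n_direct <- min(n_direct, length(ids))
      picked <- sample.int(length(ids), n_direct, prob = wgt)
      y[i, picked] <- 1L
    }
    propagate_true_path(y, dag)
  })
}

#' Protein-signal specification
#'
#' @param d Protein feature dimension (>= 2).
#' @param noise_sd Gaussian noise standard deviation added to each feature.
#' @param seed Integer seed.
#' @return List of class `po2go_signal_spec`.
#' @export
signal_spec <- function(d = 32L, noise_sd = 0.1, seed = 0L) {
  stopifnot(is_count(d), d >= 2, is.numeric(noise_sd), noise_sd >= 0)
  structure(list(d = as.integer(d), noise_sd = noise_sd, seed = as.integer(seed)),
            class = "po2go_signal_spec")
}

#' Generate protein feature vectors carrying annotation signal
#'
#' Draws a hidden Gaussian loading vector per term, then sets each protein's
#' feature vector to the mean of the loadings of its (true-path-closed) true
#' terms plus isotropic Gaussian noise — a linear, recoverable analogue of
#' mean-pooled language-model features, so predictor recovery on this data
#' is meaningful.
#'
#' @param y Binary annotation matrix (proteins x terms).
#' @param spec A [signal_spec()].
#' @return Numeric matrix n x d with the protein rownames of `y`.
#' @export
generate_protein_vectors <- function(y, spec) {
  stopifnot(inherits(spec, "po2go_signal_spec"))
  with_seed(spec$seed, {
    loadings <- matrix(rnorm(ncol(y) * spec$d), ncol(y), spec$d,
                       dimnames = list(colnames(y), NULL))
    counts <- pmax(rowSums(y > 0), 1L)
    P <- (y %*% loadings) / counts
    P + matrix(rnorm(length(P), sd = spec$noise_sd), nrow(P), ncol(P))
  })
}

#' Generate a synthetic protein-pair benchmark
#'
#' Samples protein pairs and scores each pair by the Jaccard index of the
#' true annotation sets: `pfam_like` keeps the continuous Jaccard target,
#' `ppi_like` binarizes it at a quantile ("interacting" = 1). A proxy with
#' the defining property that annotation-set similarity is the ground truth
#' by construction.
#'
#' @param y Binary annotation matrix (>= 2 proteins with annotations).
#' @param kind `"pfam_like"` or `"ppi_like"`.
#' @param n_pairs Number of sampled pairs.
#' @param seed Integer seed.
#' @param ppi_quantile Quantile of the Jaccard targets above which a
#'   `ppi_like` pair is labelled interacting.
#' @return A tibble with columns `protein_a`, `protein_b`, `target`, of
#'   class `po2go_pair_benchmark`, with the per-protein annotation sets in
#'   attribute `annotations`.
#' @export
generate_pair_benchmark <- function(y, kind = c("pfam_like", "ppi_like"),
                                    n_pairs = 200L, seed = 0L,
                                    ppi_quantile = 0.7) {
  kind <- match.arg(kind)
  annotated <- rownames(y)[rowSums(y > 0) > 0]
  if (length(annotated) < 2L) {
    stop_po2go("benchmark needs at least 2 annotated proteins", "po2go_size_error")
  }
  sets <- lapply(stats::setNames(annotated, annotated), function(p) {
    colnames(y)[y[p, ] > 0]
  })
  with_seed(seed, {
    a <- resample(annotated, n_pairs, replace = TRUE)
    b <- resample(annotated, n_pairs, replace = TRUE)
    redo <- a == b
    while (any(redo)) {
      b[redo] <- resample(annotated, sum(redo), replace = TRUE)
      redo <- a == b
    }
    jac <- vapply(seq_len(n_pairs), function(i) {
      sa <- sets[[a[[i]]]]
      sb <- sets[[b[[i]]]]
      length(intersect(sa, sb)) / length(union(sa, sb))
    }, numeric(1))
    target <- if (kind == "pfam_like") jac else {
      as.numeric(jac > stats::quantile(jac, ppi_quantile))
    }
    structure(tibble::tibble(protein_a = a, protein_b = b, target = target),
              annotations = sets,
              kind = kind,
              class = c("po2go_pair_benchmark", class(tibble::tibble())))
  })
}
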