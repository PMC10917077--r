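#' Cosine similarity
#'
#' @param e_i,e_j Non-zero numeric vectors of equal dimension.
#' @return Scalar in \[-1, 1\].
#' @export
cosine <- function(e_i, e_j) {
  if (length(e_i) != length(e_j)) {
    stop_po2go("vectors have different dimensions", "po2go_shape_error")
  }
  ni <- sqrt(sum(e_i^2))
  nj <- sqrt(sum(e_j^2))
  if (ni == 0 || nj == 0) {
    stop_po2go("cosine similarity undefined for the zero vector",
               "po2go_undefined_similarity")
  }
  sum(e_i * e_j) / (ni * nj)
}

# row-normalized embedding matrix
normalize_rows <- function(E) {
  n <- sqrt(rowSums(E^2))
  if (any(n == 0)) {
    stop_po2go("embedding contains a zero vector", "po2go_undefined_similarity")
  }
  E / n
}

#' Ancestor vs non-ancestor cosine similarity samples
#'
#' Draws `n_pairs` (term, ancestor) pairs and `n_pairs` same-domain
#' (term, non-ancestor) pairs — a non-ancestor partner is neither an ancestor
#' nor a descendant of the term — and returns the cosine similarity samples
#' for each. Non-ancestor pairs are restricted to the same domain so the
#' contrast reflects hierarchy, not trivial cross-domain separation.
#'
#' @param dag An [ontology_dag].
#' @param emb An [embedding_table()] covering the dag's active terms.
#' @param n_pairs Pairs per sample (subsampled when pools are larger).
#' @param seed Integer seed.
#' @return A list of two `similarity_sample` objects (`values`, `label`):
#'   `ancestor` and `non_ancestor`.
#' @export
ancestor_similarity_distributions <- function(dag, emb, n_pairs = 2000L, seed = 1L) {
  ids <- active_terms(dag)
  E <- normalize_rows(emb_mat(emb)[ids, , drop = FALSE])
  A <- ancestor_closure_matrix(dag) # A[t, a] = 1 iff a == t or ancestor of t
  diag(A) <- 0L
  anc_pairs <- which(A == 1L, arr.ind = TRUE) # (term, ancestor)
  dom <- dag$terms$domain[match(ids, dag$terms$term_id)]
  same_dom <- outer(dom, dom, "==")
  related <- (A + t(A)) > 0L
  non_pairs <- which(same_dom & !related & upper.tri(same_dom), arr.ind = TRUE)
  if (nrow(anc_pairs) == 0L || nrow(non_pairs) == 0L) {
    stop_po2go("ontology too small to form ancestor and non-ancestor pairs",
               "po2go_size_error")
  }
  with_seed(seed, {
    ai <- resample(seq_len(nrow(anc_pairs)), min(n_pairs, nrow(anc_pairs)))
    ni <- resample(seq_len(nrow(non_pairs)), min(n_pairs, nrow(non_pairs)))
    anc_vals <- rowSums(E[anc_pairs[ai, 1], , drop = FALSE] *
                          E[anc_pairs[ai, 2], , drop = FALSE])
    non_vals <- rowSums(E[non_pairs[ni, 1], , drop = FALSE] *
                          E[non_pairs[ni, 2], , drop = FALSE])
    list(
      ancestor = similarity_sample(anc_vals, "ancestor"),
      non_ancestor = similarity_sample(non_vals, "non_ancestor")
    )
  })
}

#' A labelled sample of similarity values
#' @param values Finite numeric vector in \[-1, 1\].
#' @param label A label string (e.g. "ancestor", "interacting").
#' @return List of class `similarity_sample`.
#' @export
similarity_sample <- function(values, label) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  structure(list(values = as.numeric(values), label = label),
            class = "similarity_sample")
}

#' 1-Wasserstein distance between two empirical distributions
#'
#' For one-dimensional samples this is the L1 distance between the two
#' empirical CDFs; with equal sample sizes it reduces to the mean absolute
#' difference of the sorted samples.
#'
#' @param a,b Non-empty numeric vectors (or `similarity_sample` objects).
#' @return Non-negative scalar.
#' @export
wasserstein_1 <- function(a, b) {
  if (inherits(a, "similarity_sample")) a <- a$values
  if (inherits(b, "similarity_sample")) b <- b$values
  if (length(a) == 0L || length(b) == 0L) {
    stop_po2go("wasserstein_1 needs non-empty samples", "po2go_size_error")
  }
  if (length(a) == length(b)) {
    return(mean(abs(sort(a) - sort(b))))
  }
  xs <- sort(unique(c(a, b)))
  Fa <- ecdf(a)(xs)
  Fb <- ecdf(b)(xs)
  sum(abs(Fa - Fb)[-length(xs)] * diff(xs))
}

#' Depth probe: can a small regressor read term depth off the embedding?
#'
#' Randomly splits the terms 80/20, fits a single-hidden-layer perceptron
#' (via `nnet`) regressing depth on the embedding, and reports held-out MSE
#' and Spearman rank correlation between predicted and true depths.
#'
#' @param emb An [embedding_table()].
#' @param depths Named integer vector of term depths (see [term_depths()]).
#' @param split_seed Seed for the 80/20 split and the probe's weights.
#' @param hidden Hidden layer width.
#' @param maxit Optimizer iteration cap.
#' @return A tibble with columns `mse`, `spearman`, `n_train`, `n_test`.
#'   With constant depths the probe is skipped: `mse` 0 for the constant
#'   predictor and `spearman` `NA`.
#' @export
depth_probe <- function(emb, depths, split_seed = 1L, hidden = 16L, maxit = 300L) {
  ids <- intersect(rownames(emb), names(depths))
  if (length(ids) < 50L) {
    stop_po2go("depth probe needs at least 50 embedded terms", "po2go_size_error")
  }
  E <- emb_mat(emb)[ids, , drop = FALSE]
  y <- as.numeric(depths[ids])
  if (stats::var(y) == 0) {
    return(tibble::tibble(mse = 0, spearman = NA_real_,
                          n_train = length(ids), n_test = 0L))
  }
  with_seed(split_seed, {
    n <- length(ids)
    test <- resample(seq_len(n), floor(0.2 * n))
    train <- setdiff(seq_len(n), test)
    mu <- colMeans(E[train, , drop = FALSE])
    sdv <- pmax(apply(E[train, , drop = FALSE], 2, sd), 1e-8)
    Xtr <- sweep(sweep(E[train, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(E[test, , drop = FALSE], 2, mu), 2, sdv, "/")
    ymax <- max(y[train])
    fit <- nnet::nnet(Xtr, y[train] / ymax, size = hidden, linout = TRUE,
                      maxit = maxit, trace = FALSE, decay = 1e-4,
                      MaxNWts = 100000L)
    pred <- as.numeric(predict(fit, Xte)) * ymax
    tibble::tibble(
      mse = mean((pred - y[test])^2),
      spearman = suppressWarnings(cor(pred, y[test], method = "spearman")),
      n_train = length(train), n_test = length(test)
    )
  })
}

#' Best-match-average semantic similarity between two annotation sets
#'
#' `0.5 * [ mean over A of the best cosine match in B + mean over B of the
#' best cosine match in A ]`, computed on the term embeddings. Symmetric.
#'
#' @param annots_a,annots_b Non-empty character vectors of term ids.
#' @param emb An [embedding_table()] covering all terms used.
#' @return Scalar in \[-1, 1\].
#' @export
bma_similarity <- function(annots_a, annots_b, emb) {
  if (length(annots_a) == 0L || length(annots_b) == 0L) {
    stop_po2go("BMA similarity needs non-empty annotation sets",
               "po2go_annotation_error")
  }
  miss <- setdiff(c(annots_a, annots_b), rownames(emb))
  if (length(miss)) {
    stop_po2go(sprintf("term not embedded: %s", miss[1]), "po2go_lookup_error")
  }
  E <- normalize_rows(emb_mat(emb))
  S <- E[annots_a, , drop = FALSE] %*% t(E[annots_b, , drop = FALSE])
  (mean(apply(S, 1, max)) + mean(apply(S, 2, max))) / 2
}

#' Pearson and Spearman correlation of two score vectors
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return A tibble with columns `pearson`, `spearman`, `n`.
#' @export
correlation_report <- function(x, y) {
  if (length(x) != length(y)) {
    stop_po2go("x and y must have equal length", "po2go_shape_error")
  }
  if (length(x) < 3L) {
    stop_po2go("correlation needs at least 3 observations", "po2go_size_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_po2go("correlation undefined for constant input",
               "po2go_degenerate_correlation")
  }
  tibble::tibble(
    pearson = cor(x, y, method = "pearson"),
    spearman = cor(x, y, method = "spearman"),
    n = length(x)
  )
}

#' Domain separation score
#'
#' Mean silhouette width of the domain labels under cosine distance in the
#' native embedding space — a quantitative stand-in for eyeballing a 2-d
#' projection. Near 1 means domains form tight separated clusters; near 0
#' means no structure.
#'
#' @param emb An [embedding_table()].
#' @param domains Named character vector term id -> domain.
#' @return Scalar in \[-1, 1\].
#' @export
domain_separation <- function(emb, domains) {
  ids <- intersect(rownames(emb), names(domains))
  dom <- domains[ids]
  if (length(unique(dom)) < 2L) {
    stop_po2go("domain separation needs at least 2 domains", "po2go_config_error")
  }
  if (any(table(dom) < 2L)) {
    stop_po2go("every domain needs at least 2 terms", "po2go_config_error")
  }
  E <- normalize_rows(emb_mat(emb)[ids, , drop = FALSE])
  dmat <- 1 - E %*% t(E) # cosine distance
  dmat[dmat < 0] <- 0
  sil <- cluster::silhouette(as.integer(factor(dom)), dmatrix = dmat)
  mean(sil[, "sil_width"])
}

#' 2-d projection hook for external plotting
#'
#' Principal-component projection of the (row-normalized) embedding onto two
#' dimensions, returned as a tibble for downstream plotting tools.
#'
#' @param emb An [embedding_table()].
#' @param domains Optional named character vector term id -> domain.
#' @return Tibble with columns `term_id`, `x`, `y` (and `domain` if given).
#' @export
project_2d <- function(emb, domains = NULL) {
  E <- normalize_rows(emb_mat(emb))
  p <- stats::prcomp(E, rank. = 2L)
  out <- tibble::tibble(term_id = rownames(E),
                        x = p$x[, 1], y = p$x[, 2])
  if (!is.null(domains)) out$domain <- unname(domains[out$term_id])
  out
}
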