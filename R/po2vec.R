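#' Training configuration for term embeddings
#'
#' @param tau Temperature for the similarity kernel (> 0).
#' @param d_prime Embedding dimension (>= 2).
#' @param epochs Number of passes over the term set.
#' @param batch_size Anchors per gradient step (1 = pure per-anchor SGD;
#'   larger values accumulate gradients before applying them).
#' @param learning_rate SGD step size.
#' @param seed Seed for embedding initialization.
#' @param sim_variant `"scaled"` for `exp(dot/tau)` (the standard InfoNCE
#'   temperature placement, the default) or `"literal"` for `exp(dot)/tau`.
#'   Under the literal reading `tau` cancels out of the balanced loss and its
#'   gradients, so it only rescales reported similarities.
#' @return A list of class `po2go_train_config`.
#' @export
train_config <- function(tau = 0.1, d_prime = 128L, epochs = 100L,
                         batch_size = 1L, learning_rate = 1e-3, seed = 1L,
                         sim_variant = c("scaled", "literal")) {
  stopifnot(is.numeric(tau), tau > 0, is_count(d_prime), d_prime >= 2,
            is_count(epochs), is_count(batch_size),
            is.numeric(learning_rate), learning_rate > 0)
  structure(list(tau = tau, d_prime = as.integer(d_prime),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 sim_variant = match.arg(sim_variant)),
            class = "po2go_train_config")
}

# effective temperature dividing the dot product
tau_eff <- function(tau, sim_variant) if (sim_variant == "scaled") tau else 1

#' Pairwise similarity kernel
#'
#' `exp(dot(e_i, e_j) / tau)` under the default `"scaled"` variant, or the
#' literal `exp(dot(e_i, e_j)) / tau` under `"literal"`.
#'
#' @param e_i,e_j Numeric vectors of equal length.
#' @param tau Positive temperature.
#' @param sim_variant `"scaled"` or `"literal"`.
#' @return A positive scalar.
#' @export
pair_similarity <- function(e_i, e_j, tau, sim_variant = c("scaled", "literal")) {
  sim_variant <- match.arg(sim_variant)
  if (length(e_i) != length(e_j)) {
    stop_po2go("embedding vectors have different dimensions", "po2go_shape_error")
  }
  stopifnot(tau > 0)
  d <- sum(e_i * e_j)
  if (sim_variant == "scaled") exp(d / tau) else exp(d) / tau
}

#' Embedding table constructor
#'
#' @param matrix Numeric matrix, one row per term, rownames = term ids.
#' @return The matrix with class `po2go_embedding`.
#' @export
embedding_table <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix), !is.null(rownames(matrix)))
  if (anyDuplicated(rownames(matrix))) {
    stop_po2go("duplicated term_id in embedding table", "po2go_format_error")
  }
  if (!all(is.finite(matrix))) {
    stop_po2go("embedding table contains non-finite values", "po2go_format_error")
  }
  class(matrix) <- c("po2go_embedding", class(matrix))
  matrix
}

# strip class for arithmetic
emb_mat <- function(emb) {
  m <- unclass(emb)
  class(m) <- NULL
  dim(m) <- dim(emb)
  dimnames(m) <- dimnames(emb)
  m
}

#' Balanced InfoNCE loss
#'
#' For each anchor `t` with positive `t+` and stratified negative sets
#' `N_dr`, `N_ir`, `N_ur`, the per-anchor loss is
#' `-log( sim(e_t, e_t+) / (sim(e_t, e_t+) + C) )` where the balancing term
#' `C` is `k/B` times the sum over the `B` non-empty classes of the class
#' mean similarity, so the scarce direct class carries the same weight as the
#' abundant indirect and unreachable classes. The batch reduction is the sum.
#' Computed in log space for numerical stability.
#'
#' @param emb An [embedding_table()].
#' @param anchors A list of anchors, each a list with elements `t`, `t_pos`,
#'   `N_dr`, `N_ir`, `N_ur` (term ids; class vectors may be empty).
#' @param cfg A [train_config()] (uses `tau` and `sim_variant`).
#' @param k Total negative count the class weights refer to; default the
#'   summed class sizes per anchor.
#' @return Non-negative scalar loss (sum over anchors).
#' @export
balanced_infonce_loss <- function(emb, anchors, cfg, k = NULL) {
  E <- emb_mat(emb)
  total <- 0
  for (a in anchors) {
    total <- total + anchor_loss_grad(E, a, cfg, k = k, want_grad = FALSE)$loss
  }
  total
}

# Per-anchor loss and (optionally) gradients, in log space.
# Returns list(loss, gi, gpos, gneg (list per class), idx (list per class), ipos, ianchor)
anchor_loss_grad <- function(E, a, cfg, k = NULL, want_grad = TRUE) {
  te <- tau_eff(cfg$tau, cfg$sim_variant)
  ids <- rownames(E)
  it <- match(a$t, ids)
  ip <- match(a$t_pos, ids)
  classes <- list(a$N_dr, a$N_ir, a$N_ur)
  sizes <- vapply(classes, length, integer(1))
  nonempty <- which(sizes > 0L)
  if (length(nonempty) == 0L) {
    stop_po2go(sprintf("anchor %s: all three negative classes empty", a$t),
               "po2go_degenerate_anchor")
  }
  kk <- k %||% sum(sizes)
  idx <- lapply(classes[nonempty], function(x) match(x, ids))
  if (anyNA(it) || anyNA(ip) || anyNA(unlist(idx))) {
    stop_po2go(sprintf("anchor %s references a term missing from the embedding", a$t),
               "po2go_lookup_error")
  }
  ei <- E[it, ]
  zp <- sum(ei * E[ip, ]) / te
  zneg <- lapply(idx, function(ii) as.numeric(E[ii, , drop = FALSE] %*% ei) / te)
  # per-sample log weights: log(k/B) - log(|class|)
  B <- length(nonempty)
  logw <- lapply(seq_along(idx), function(c) {
    rep(log(kk / B) - log(length(idx[[c]])), length(idx[[c]]))
  })
  allz <- c(zp, unlist(zneg) + unlist(logw))
  M <- max(allz)
  S <- sum(exp(allz - M))
  loss <- -zp + M + log(S)
  if (!is.finite(loss)) {
    stop_po2go(sprintf("non-finite loss at anchor %s", a$t), "po2go_numeric_error")
  }
  if (!want_grad) return(list(loss = loss))
  # dL/dz_p = -1 + softmax share of the positive; dL/dz_n = its softmax share
  pp <- exp(zp - M) / S
  dzp <- pp - 1
  gneg <- vector("list", length(idx))
  gi <- dzp * E[ip, ]
  for (c in seq_along(idx)) {
    share <- exp(zneg[[c]] + logw[[c]] - M) / S
    gneg[[c]] <- (share / te) %o% ei
    gi <- gi + as.numeric(share %*% E[idx[[c]], , drop = FALSE])
  }
  list(loss = loss, gi = gi / te, gpos = dzp * ei / te, gneg = gneg,
       idx = idx, ipos = ip, ianchor = it)
}

#' Train term embeddings by partial-order contrastive learning
#'
#' Initializes a term embedding table with i.i.d. Gaussian entries
#' (sd = 1/sqrt(d')) and minimizes the balanced InfoNCE loss by stochastic
#' gradient descent. Each epoch visits every term once as anchor in a
#' shuffled order, drawing a fresh positive and fresh stratified negatives.
#' Fully deterministic given `cfg$seed` (initialization) and
#' `sampler_cfg$seed` (the sampling/training stream).
#'
#' @param dag An [ontology_dag] with at least 2 terms per domain.
#' @param cfg A [train_config()].
#' @param sampler_cfg A [sampler_config()].
#' @param index Optionally a prebuilt [build_index()] for `dag`.
#' @return An object of class `po2vec_fit`: list with `embedding` (an
#'   [embedding_table()]), `history` (tibble of per-epoch mean loss),
#'   `config`, `sampler_config`.
#' @export
train_embeddings <- function(dag, cfg = train_config(),
                             sampler_cfg = sampler_config(), index = NULL) {
  index <- index %||% build_index(dag)
  ids <- index$term_ids
  m <- length(ids)
  counts <- table(index$domains)
  if (any(counts < 2L)) {
    stop_po2go("every domain needs at least 2 terms for contrastive training",
               "po2go_structure_error")
  }
  E <- with_seed(cfg$seed, matrix(rnorm(m * cfg$d_prime, sd = 1 / sqrt(cfg$d_prime)),
                                  m, cfg$d_prime, dimnames = list(ids, NULL)))
  lr <- cfg$learning_rate
  hist_loss <- numeric(cfg$epochs)
  with_seed(sampler_cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      order_ids <- resample(seq_len(m), m)
      ep_loss <- 0
      n_seen <- 0L
      acc <- NULL
      n_in_batch <- 0L
      for (i in order_ids) {
        t_id <- ids[[i]]
        if (length(index$pos[[i]]) == 0L) next
        t_pos <- sample_positive(index, t_id)
        negs <- suppressWarnings(sample_negatives(index, t_id, t_pos, sampler_cfg))
        if (length(negs$N_dr) + length(negs$N_ir) + length(negs$N_ur) == 0L) {
          next # no eligible negatives for this anchor (tiny single-domain DAGs)
        }
        a <- list(t = t_id, t_pos = t_pos,
                  N_dr = negs$N_dr, N_ir = negs$N_ir, N_ur = negs$N_ur)
        g <- anchor_loss_grad(E, a, cfg, k = sampler_cfg$k)
        ep_loss <- ep_loss + g$loss
        n_seen <- n_seen + 1L
        if (cfg$batch_size == 1L) {
          E[g$ianchor, ] <- E[g$ianchor, ] - lr * g$gi
          E[g$ipos, ] <- E[g$ipos, ] - lr * g$gpos
          for (c in seq_along(g$idx)) {
            E[g$idx[[c]], ] <- E[g$idx[[c]], , drop = FALSE] - lr * g$gneg[[c]]
          }
        } else {
          if (is.null(acc)) acc <- matrix(0, m, cfg$d_prime)
          acc[g$ianchor, ] <- acc[g$ianchor, ] + g$gi
          acc[g$ipos, ] <- acc[g$ipos, ] + g$gpos
          for (c in seq_along(g$idx)) {
            acc[g$idx[[c]], ] <- acc[g$idx[[c]], , drop = FALSE] + g$gneg[[c]]
          }
          n_in_batch <- n_in_batch + 1L
          if (n_in_batch == cfg$batch_size) {
            E <- E - lr * acc
            acc[] <- 0
            n_in_batch <- 0L
          }
        }
      }
      if (!is.null(acc) && n_in_batch > 0L) E <- E - lr * acc
      hist_loss[[ep]] <- ep_loss / max(n_seen, 1L)
    }
  })
  structure(
    list(embedding = embedding_table(E),
         history = tibble::tibble(epoch = seq_len(cfg$epochs),
                                  mean_loss = hist_loss),
         config = cfg, sampler_config = sampler_cfg),
    class = "po2vec_fit"
  )
}

#' @export
print.po2vec_fit <- function(x, ...) {
  cat(sprintf("<po2vec_fit> %d terms x %d dims, %d epochs (mean loss %.4f -> %.4f)\n",
              nrow(x$embedding), ncol(x$embedding), nrow(x$history),
              x$history$mean_loss[[1]], x$history$mean_loss[[nrow(x$history)]]))
  invisible(x)
}

#' Random embedding baseline
#'
#' The same i.i.d. Gaussian initialization used by [train_embeddings()], with
#' no training — the seed-matched baseline for all embedding-quality
#' comparisons.
#'
#' @param dag An [ontology_dag].
#' @param d_prime Embedding dimension.
#' @param seed Integer seed.
#' @return An [embedding_table()].
#' @export
random_embeddings <- function(dag, d_prime = 128L, seed = 1L) {
  ids <- active_terms(dag)
  E <- with_seed(seed, matrix(rnorm(length(ids) * d_prime, sd = 1 / sqrt(d_prime)),
                              length(ids), d_prime, dimnames = list(ids, NULL)))
  embedding_table(E)
}

#' Save / load a term embedding table
#'
#' Plain-text format: a header line `#po2vec d_prime=<int> m=<int>` followed
#' by one `term_id<TAB>v1...v_d'` line per term with 17-significant-digit
#' decimals, so a round trip reproduces the table exactly.
#'
#' @param emb An [embedding_table()].
#' @param path File path.
#' @return `save_embeddings`: `path` invisibly. `load_embeddings`: an
#'   [embedding_table()].
#' @export
save_embeddings <- function(emb, path) {
  E <- emb_mat(emb)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#po2vec d_prime=%d m=%d", ncol(E), nrow(E)), con)
  body <- vapply(seq_len(nrow(E)), function(i) {
    paste(c(rownames(E)[[i]], sprintf("%.17g", E[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hd <- regmatches(lines[[1]],
                   regexec("^#po2vec d_prime=(\\d+) m=(\\d+)$", lines[[1]]))[[1]]
  if (length(hd) != 3L) {
    stop_po2go("missing or malformed #po2vec header", "po2go_format_error")
  }
  d <- as.integer(hd[[2]])
  m <- as.integer(hd[[3]])
  body <- lines[-1]
  if (length(body) != m) {
    stop_po2go(sprintf("header says m=%d but file has %d rows", m, length(body)),
               "po2go_format_error")
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) != d + 1L)) {
    stop_po2go("row width does not match d_prime", "po2go_format_error")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_po2go(sprintf("duplicated term_id in embedding file: %s",
                       ids[duplicated(ids)][1]), "po2go_format_error")
  }
  E <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(d)))
  if (d == 1L) E <- matrix(E, ncol = 1L)
  rownames(E) <- ids
  embedding_table(E)
}

#' Partial-order constraint satisfaction rate
#'
#' Samples triples (anchor i, j, k) with `srp(i, j) < srp(i, k)` and reports
#' the fraction for which the embedding agrees, i.e.
#' `cosine(e_i, e_j) >= cosine(e_i, e_k)`. Trained embeddings should beat the
#' seed-matched random baseline.
#'
#' @param emb An [embedding_table()].
#' @param index A [build_index()] for the same ontology.
#' @param n_triples Number of triples to sample.
#' @param seed Integer seed.
#' @return A scalar fraction in \[0, 1\].
#' @export
partial_order_satisfaction <- function(emb, index, n_triples = 10000L, seed = 1L) {
  E <- emb_mat(emb)[index$term_ids, , drop = FALSE]
  En <- E / sqrt(rowSums(E^2))
  S <- index$srp
  m <- nrow(S)
  with_seed(seed, {
    kept <- 0L
    sat <- 0L
    while (kept < n_triples) {
      take <- (n_triples - kept) * 2L
      i <- sample.int(m, take, replace = TRUE)
      j <- sample.int(m, take, replace = TRUE)
      k <- sample.int(m, take, replace = TRUE)
      ok <- i != j & i != k & j != k
      sij <- S[cbind(i, j)]
      sik <- S[cbind(i, k)]
      ok <- ok & (sij != sik) & (is.finite(sij) | is.finite(sik))
      i <- i[ok]; j <- j[ok]; k <- k[ok]
      sij <- sij[ok]; sik <- sik[ok]
      swap <- sij > sik
      tmp <- j[swap]; j[swap] <- k[swap]; k[swap] <- tmp
      n_take <- min(length(i), n_triples - kept)
      if (n_take > 0L) {
        ii <- seq_len(n_take)
        cj <- rowSums(En[i[ii], , drop = FALSE] * En[j[ii], , drop = FALSE])
        ck <- rowSums(En[i[ii], , drop = FALSE] * En[k[ii], , drop = FALSE])
        sat <- sat + sum(cj >= ck)
        kept <- kept + n_take
      }
    }
    sat / kept
  })
}
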