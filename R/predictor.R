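#' Predictor configuration
#'
#' @param hidden Hidden width of the two projection perceptrons.
#' @param h Shared projection dimension.
#' @param epochs Full-batch Adam epochs.
#' @param learning_rate Adam step size.
#' @param freeze_terms If `TRUE` the term embedding table is frozen during
#'   training (the fixed-embedding ablation); by default it is tuned.
#' @param seed Seed for weight initialization.
#' @return List of class `po2go_predictor_config`.
#' @export
predictor_config <- function(hidden = 64L, h = 32L, epochs = 200L,
                             learning_rate = 5e-3, freeze_terms = FALSE,
                             seed = 1L) {
  stopifnot(is_count(hidden), is_count(h), is_count(epochs),
            learning_rate > 0, is.logical(freeze_terms))
  structure(list(hidden = as.integer(hidden), h = as.integer(h),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 freeze_terms = freeze_terms, seed = as.integer(seed)),
            class = "po2go_predictor_config")
}

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

init_predictor <- function(d, d_prime, m, cfg) {
  with_seed(cfg$seed, list(
    W1p = glorot(d, cfg$hidden), b1p = numeric(cfg$hidden),
    W2p = glorot(cfg$hidden, cfg$h), b2p = numeric(cfg$h),
    W1t = glorot(d_prime, cfg$hidden), b1t = numeric(cfg$hidden),
    W2t = glorot(cfg$hidden, cfg$h), b2t = numeric(cfg$h),
    W3 = glorot(m, m), b3 = numeric(m)
  ))
}

mlp_forward <- function(X, W1, b1, W2, b2) {
  H <- sweep(X %*% W1, 2, b1, "+")
  A <- pmax(H, 0)
  list(H = H, A = A, out = sweep(A %*% W2, 2, b2, "+"))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Joint protein-term scores
#'
#' Projects the model's term table and a protein feature vector into the
#' shared space and returns the m dot products
#' `s_j = e_proj(t_j)' f_proj(p)`.
#'
#' @param model A trained or initialized `po2go_model`.
#' @param f_p Protein feature vector of the model's input dimension.
#' @return Numeric vector of length m (named by term id).
#' @export
joint_scores <- function(model, f_p) {
  if (length(f_p) != model$d) {
    stop_po2go("protein vector dimension mismatch", "po2go_shape_error")
  }
  w <- model$weights
  Fp <- mlp_forward(matrix(f_p, 1), w$W1p, w$b1p, w$W2p, w$b2p)$out
  Ep <- mlp_forward(model$term_matrix, w$W1t, w$b1t, w$W2t, w$b2t)$out
  stats::setNames(as.numeric(Ep %*% t(Fp)), rownames(model$term_matrix))
}

#' Multi-label binary cross-entropy
#'
#' `-sum_j [ y_j log(yhat_j) + (1 - y_j) log(1 - yhat_j) ]`. Predictions at
#' exactly 0 or 1 are clamped to `eps` / `1 - eps`.
#'
#' @param y_hat Numeric vector/matrix of predictions in \[0, 1\].
#' @param y Binary labels of the same shape.
#' @param eps Clamp width.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y_hat, y, eps = 1e-12) {
  if (length(y_hat) != length(y)) {
    stop_po2go("prediction/label length mismatch", "po2go_shape_error")
  }
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

predictor_forward <- function(weights, P, TermE) {
  fp <- mlp_forward(P, weights$W1p, weights$b1p, weights$W2p, weights$b2p)
  ft <- mlp_forward(TermE, weights$W1t, weights$b1t, weights$W2t, weights$b2t)
  S <- fp$out %*% t(ft$out) # n x m
  Z <- sweep(S %*% t(weights$W3), 2, weights$b3, "+")
  list(fp = fp, ft = ft, S = S, Z = Z, Yhat = sigmoid(Z))
}

#' Train the joint predictor
#'
#' Freezes the protein feature vectors, then learns the two projection
#' perceptrons and the output layer — and, unless `cfg$freeze_terms`, tunes
#' the term embedding table itself — by full-batch Adam on the multi-label
#' binary cross-entropy. Deterministic given `cfg$seed`.
#'
#' @param proteins Numeric matrix n x d of fixed protein feature vectors
#'   (rownames = protein ids).
#' @param y Binary annotation matrix n x m, true-path closed, columns
#'   matching `emb` rows.
#' @param emb An [embedding_table()] of term vectors (m x d').
#' @param cfg A [predictor_config()].
#' @return An object of class `po2go_model` with elements `weights`,
#'   `term_matrix` (tuned copy), `history` (tibble epoch/loss), `config`,
#'   `d`, `term_ids`.
#' @export
train_predictor <- function(proteins, y, emb, cfg = predictor_config()) {
  stopifnot(is.matrix(proteins), is.matrix(y))
  ids <- colnames(y)
  if (!setequal(ids, rownames(emb))) {
    stop_po2go("annotation columns and embedded terms differ", "po2go_shape_error")
  }
  if (nrow(proteins) != nrow(y)) {
    stop_po2go("protein and annotation row counts differ", "po2go_shape_error")
  }
  TermE <- emb_mat(emb)[ids, , drop = FALSE]
  P <- proteins
  n <- nrow(P)
  m <- ncol(y)
  w <- init_predictor(ncol(P), ncol(TermE), m, cfg)
  params <- c(names(w), if (!cfg$freeze_terms) "TermE")
  adam_m <- adam_v <- lapply(stats::setNames(params, params), function(nm) {
    x <- if (nm == "TermE") TermE else w[[nm]]
    array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  losses <- numeric(cfg$epochs)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    fw <- predictor_forward(w, P, TermE)
    loss <- bce_loss(fw$Yhat, y)
    if (!is.finite(loss)) {
      stop_po2go(sprintf("divergent loss at epoch %d", ep), "po2go_numeric_error")
    }
    losses[[ep]] <- loss / n
    dZ <- fw$Yhat - y # n x m
    grads <- list(
      W3 = t(dZ) %*% fw$S, b3 = colSums(dZ)
    )
    dS <- dZ %*% w$W3 # n x m
    dFp <- dS %*% ft_out(fw) # n x h
    dFt <- t(dS) %*% fp_out(fw) # m x h
    # protein head
    gp <- mlp_backward(dFp, fw$fp, P, w$W1p, w$W2p)
    grads$W2p <- gp$dW2; grads$b2p <- gp$db2
    grads$W1p <- gp$dW1; grads$b1p <- gp$db1
    # term head
    gt <- mlp_backward(dFt, fw$ft, TermE, w$W1t, w$W2t)
    grads$W2t <- gt$dW2; grads$b2t <- gt$db2
    grads$W1t <- gt$dW1; grads$b1t <- gt$db1
    if (!cfg$freeze_terms) grads$TermE <- gt$dX
    step <- step + 1L
    for (nm in names(grads)) {
      g <- grads[[nm]]
      adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
      adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
      mhat <- adam_m[[nm]] / (1 - beta1^step)
      vhat <- adam_v[[nm]] / (1 - beta2^step)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (nm == "TermE") TermE <- TermE - upd else w[[nm]] <- w[[nm]] - upd
    }
  }
  structure(
    list(weights = w, term_matrix = TermE, term_ids = ids, d = ncol(P),
         history = tibble::tibble(epoch = seq_len(cfg$epochs),
                                  mean_loss = losses),
         config = cfg),
    class = "po2go_model"
  )
}

fp_out <- function(fw) fw$fp$out
ft_out <- function(fw) fw$ft$out

mlp_backward <- function(dOut, cache, X, W1, W2) {
  dW2 <- t(cache$A) %*% dOut
  db2 <- colSums(dOut)
  dA <- dOut %*% t(W2)
  dH <- dA * (cache$H > 0)
  list(dW2 = dW2, db2 = db2, dW1 = t(X) %*% dH, db1 = colSums(dH),
       dX = dH %*% t(W1))
}

#' @export
print.po2go_model <- function(x, ...) {
  cat(sprintf("<po2go_model> %d terms, protein dim %d, %d epochs (loss %.4f -> %.4f)\n",
              length(x$term_ids), x$d, nrow(x$history),
              x$history$mean_loss[[1]], x$history$mean_loss[[nrow(x$history)]]))
  invisible(x)
}

#' Predict annotation scores for proteins
#'
#' @param object A `po2go_model`.
#' @param proteins Matrix n x d of protein feature vectors (or a single
#'   vector).
#' @param ... Unused.
#' @return Matrix n x m of scores strictly inside (0, 1).
#' @export
predict.po2go_model <- function(object, proteins, ...) {
  if (is.null(dim(proteins))) proteins <- matrix(proteins, 1)
  if (ncol(proteins) != object$d) {
    stop_po2go("protein vector dimension mismatch", "po2go_shape_error")
  }
  fw <- predictor_forward(object$weights, proteins, object$term_matrix)
  out <- fw$Yhat
  if (!all(is.finite(out))) stop_po2go("non-finite prediction", "po2go_numeric_error")
  dimnames(out) <- list(rownames(proteins), object$term_ids)
  out
}

#' Label-prior baseline scores
#'
#' Every protein receives each term's training prevalence as its score — the
#' no-information baseline all trained predictors must beat.
#'
#' @param y Binary annotation matrix (training labels).
#' @param n Number of rows to emit (default `nrow(y)`).
#' @return Matrix n x m of constant per-term scores.
#' @export
label_prior_scores <- function(y, n = nrow(y)) {
  prior <- colMeans(y > 0)
  matrix(prior, n, ncol(y), byrow = TRUE,
         dimnames = list(NULL, colnames(y)))
}

#' Multi-hot term features (ablation)
#'
#' Each term is represented by the indicator vector of itself and its
#' ancestors — the naive hierarchy-aware embedding used as an ablation
#' reference for the learned table.
#'
#' @param dag An [ontology_dag].
#' @return An [embedding_table()] of dimension m x m.
#' @export
multi_hot_embedding <- function(dag) {
  A <- ancestor_closure_matrix(dag)
  storage.mode(A) <- "double"
  embedding_table(A)
}

#' Deterministic toy protein embedder
#'
#' Hash-seeded per-residue base vectors, mean-pooled over the sequence. A
#' stand-in for a real protein language model: purely deterministic test
#' plumbing with no biological content.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet (`X`
#'   tolerated).
#' @param d Output dimension.
#' @return Numeric vector of length `d`.
#' @export
toy_protein_embedder <- function(sequence, d = 32L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(chars, alphabet)
  if (length(bad)) {
    stop_po2go(sprintf("illegal amino-acid character: %s", bad[1]),
               "po2go_input_error")
  }
  base <- vapply(alphabet, function(a) {
    with_seed(7919L * as.integer(d) + utf8ToInt(a), rnorm(d))
  }, numeric(d))
  rowMeans(base[, match(chars, alphabet), drop = FALSE])
}
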