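# Independent brute-force oracles. These deliberately avoid the package's
# igraph/vectorized code paths: plain edge-list BFS, repeated-expansion
# closures, exhaustive threshold enumeration, permutation matching.

# all-pairs directed hop counts by BFS over a child->parent edge list
oracle_distances <- function(ids, edges) {
  D <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  diag(D) <- 0
  adj <- split(edges$parent, edges$child)
  for (s in ids) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.na(nxt) & !is.finite(D[s, nxt])]
      if (length(nxt)) D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# SRP by definition: direct via BFS in either orientation, indirect via
# explicit enumeration over every common ancestor, else Inf
oracle_srp <- function(ids, edges, a, b) {
  if (a == b) return(list(length = 0, reachability = "direct"))
  D <- oracle_distances(ids, edges)
  if (is.finite(D[a, b]) || is.finite(D[b, a])) {
    return(list(length = min(D[a, b], D[b, a]), reachability = "direct"))
  }
  best <- Inf
  for (k in ids) {
    if (k != a && k != b && is.finite(D[a, k]) && is.finite(D[b, k])) {
      best <- min(best, D[a, k] + D[b, k])
    }
  }
  if (is.finite(best)) list(length = best + 0.5, reachability = "indirect")
  else list(length = Inf, reachability = "unreachable")
}

oracle_srp_matrix <- function(dag) {
  ids <- active_terms(dag)
  D <- oracle_distances(ids, dag$edges)
  S <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) { S[i, j] <- 0; next }
      if (is.finite(D[i, j]) || is.finite(D[j, i])) {
        S[i, j] <- min(D[i, j], D[j, i])
      } else {
        cand <- D[i, ] + D[j, ]
        cand <- cand[-c(i, j)]
        if (any(is.finite(cand))) S[i, j] <- min(cand) + 0.5
      }
    }
  }
  S
}

# ancestors by repeated single-step expansion of the edge list
oracle_ancestors <- function(edges, t) {
  anc <- character()
  frontier <- t
  repeat {
    parents <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(parents, anc)
    if (length(new) == 0L) break
    anc <- c(anc, new)
    frontier <- new
  }
  setdiff(anc, t)
}

# true-path closure as an explicit per-protein ancestor union
oracle_propagate <- function(y, dag) {
  ids <- active_terms(dag)
  out <- matrix(0L, nrow(y), length(ids), dimnames = list(rownames(y), ids))
  for (i in seq_len(nrow(y))) {
    direct <- colnames(y)[y[i, ] > 0]
    full <- unique(c(direct, unlist(lapply(direct, oracle_ancestors,
                                           edges = dag$edges))))
    out[i, full] <- 1L
  }
  out
}

# scalar balanced InfoNCE per the printed formulas (no log-space tricks)
oracle_balanced_loss <- function(E, anchors, tau, k, variant = "scaled") {
  simf <- function(i, j) {
    d <- sum(E[i, ] * E[j, ])
    if (variant == "scaled") exp(d / tau) else exp(d) / tau
  }
  total <- 0
  for (a in anchors) {
    classes <- Filter(length, list(a$N_dr, a$N_ir, a$N_ur))
    B <- length(classes)
    C <- (k / B) * sum(vapply(classes, function(cl) {
      mean(vapply(cl, function(n) simf(a$t, n), numeric(1)))
    }, numeric(1)))
    sp <- simf(a$t, a$t_pos)
    total <- total - log(sp / (sp + C))
  }
  total
}

# 1-Wasserstein for equal-size samples as a minimum-cost perfect matching,
# enumerated over all permutations (n <= 6)
oracle_wasserstein_matching <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 6)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[[i]], p))
    }))
  }
  min(vapply(perms(seq_along(b)), function(p) mean(abs(a - b[p])), numeric(1)))
}

# protein-centric Fmax by explicit per-protein loops over a threshold grid
oracle_fmax <- function(scores, y, thresholds) {
  best <- 0
  for (tau in thresholds) {
    precs <- c(); recs <- c()
    for (i in seq_len(nrow(y))) {
      pred <- which(scores[i, ] >= tau)
      truth <- which(y[i, ] == 1)
      if (length(pred)) precs <- c(precs, length(intersect(pred, truth)) / length(pred))
      if (length(truth)) recs <- c(recs, length(intersect(pred, truth)) / length(truth))
    }
    p <- if (length(precs)) mean(precs) else 0
    r <- if (length(recs)) mean(recs) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    best <- max(best, f)
  }
  best
}

oracle_smin <- function(scores, y, ic, thresholds) {
  best <- Inf
  for (tau in thresholds) {
    ru <- 0; mi <- 0
    for (i in seq_len(nrow(y))) {
      pred <- colnames(y)[scores[i, ] >= tau]
      truth <- colnames(y)[y[i, ] == 1]
      ru <- ru + sum(ic[setdiff(truth, pred)])
      mi <- mi + sum(ic[setdiff(pred, truth)])
    }
    best <- min(best, sqrt((ru / nrow(y))^2 + (mi / nrow(y))^2))
  }
  best
}

# AUPR by explicit cutoff enumeration over the distinct scores
oracle_aupr <- function(scores, y) {
  s <- as.numeric(scores); lab <- as.numeric(y) > 0
  cuts <- sort(unique(s), decreasing = TRUE)
  npos <- sum(lab)
  prev_r <- 0; area <- 0
  for (cc in cuts) {
    sel <- s >= cc
    p <- sum(lab[sel]) / sum(sel)
    r <- sum(lab[sel]) / npos
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

oracle_f1_by_bin <- function(scores, y, threshold, breaks) {
  counts <- colSums(y)
  res <- list()
  for (j in which(counts >= 1)) {
    tp <- sum(scores[, j] >= threshold & y[, j] == 1)
    fp <- sum(scores[, j] >= threshold & y[, j] == 0)
    fn <- sum(scores[, j] < threshold & y[, j] == 1)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    bin <- max(which(breaks <= counts[j]))
    res[[length(res) + 1L]] <- c(bin = bin, f1 = f1)
  }
  m <- do.call(rbind, res)
  tapply(m[, "f1"], m[, "bin"], mean)
}

# small hand-buildable DAG: a diamond plus a second domain
diamond_dag <- function() {
  terms <- data.frame(
    term_id = c("d1:R", "d1:A", "d1:B", "d1:C", "d1:D", "d2:R", "d2:X"),
    domain = c(rep("dom1", 5), "dom2", "dom2")
  )
  edges <- data.frame(
    child = c("d1:A", "d1:B", "d1:C", "d1:C", "d1:D", "d2:X"),
    parent = c("d1:R", "d1:R", "d1:A", "d1:B", "d1:C", "d2:R"),
    relation = c("is_a", "is_a", "is_a", "part_of", "is_a", "is_a")
  )
  ontology_dag(terms, edges)
}
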