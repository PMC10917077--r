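check_scores <- function(scores, y) {
  if (!all(dim(scores) == dim(y))) {
    stop_po2go("scores and annotation matrix have different shapes",
               "po2go_shape_error")
  }
  if (!all(is.finite(scores))) {
    stop_po2go("scores contain non-finite values", "po2go_metric_error")
  }
}

#' CAFA threshold grid
#' @param step Grid step (default 0.01).
#' @return Numeric vector of thresholds over (0, 1].
#' @export
cafa_thresholds <- function(step = 0.01) {
  seq(step, 1, by = step)
}

#' Protein-centric Fmax
#'
#' At each threshold `tau`, precision is averaged over proteins with at
#' least one prediction `>= tau` and recall over all proteins with at least
#' one true term; Fmax is the maximum harmonic mean over the grid.
#'
#' @param scores Numeric matrix proteins x terms in \[0, 1\].
#' @param y Binary annotation matrix of the same shape (true-path closed).
#' @param thresholds Threshold grid (default [cafa_thresholds()]).
#' @return A list with `fmax`, `threshold` (the maximizing threshold),
#'   `curve` (tibble threshold/precision/recall/f).
#' @export
f_max <- function(scores, y, thresholds = cafa_thresholds()) {
  check_scores(scores, y)
  has_truth <- rowSums(y) > 0
  if (!any(has_truth)) stop_po2go("empty truth", "po2go_metric_error")
  n_eval <- sum(has_truth)
  prec <- rec <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    pred <- scores >= thresholds[[ti]]
    tp <- rowSums(pred & y == 1)
    npred <- rowSums(pred)
    covered <- npred > 0
    prec[[ti]] <- if (any(covered)) mean((tp / npred)[covered]) else 0
    rec[[ti]] <- sum((tp / rowSums(y))[has_truth]) / n_eval
  }
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  best <- which.max(f)
  list(fmax = f[[best]], threshold = thresholds[[best]],
       curve = tibble::tibble(threshold = thresholds, precision = prec,
                              recall = rec, f = f))
}

#' Smin: minimum semantic distance over thresholds
#'
#' `ru(tau)` is the average over proteins of the summed information content
#' of missed true terms, `mi(tau)` the average summed IC of wrongly
#' predicted terms; Smin is the minimum of `sqrt(ru^2 + mi^2)` over the
#' threshold grid.
#'
#' @inheritParams f_max
#' @param ic Named numeric vector of per-term information content covering
#'   every term column.
#' @return A list with `smin`, `threshold`, `curve` (tibble threshold/ru/mi/s).
#' @export
s_min <- function(scores, y, ic, thresholds = cafa_thresholds()) {
  check_scores(scores, y)
  missing_ic <- setdiff(colnames(y), names(ic))
  if (length(missing_ic)) {
    stop_po2go(sprintf("no information content for term: %s", missing_ic[1]),
               "po2go_metric_error")
  }
  icv <- as.numeric(ic[colnames(y)])
  n <- nrow(y)
  ru <- mi <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    pred <- scores >= thresholds[[ti]]
    fn <- (y == 1) & !pred
    fp <- pred & (y == 0)
    ru[[ti]] <- sum(t(fn) * icv) / n
    mi[[ti]] <- sum(t(fp) * icv) / n
  }
  s <- sqrt(ru^2 + mi^2)
  best <- which.min(s)
  list(smin = s[[best]], threshold = thresholds[[best]],
       curve = tibble::tibble(threshold = thresholds, ru = ru, mi = mi, s = s))
}

#' Micro-averaged area under the precision-recall curve
#'
#' Pools all (protein, term) cells, ranks them by score and integrates the
#' step-wise PR curve as `sum over threshold steps of (delta recall) x
#' precision` (no trapezoid interpolation). Tied scores enter as a single
#' step.
#'
#' @inheritParams f_max
#' @return Scalar in \[0, 1\].
#' @export
aupr <- function(scores, y) {
  check_scores(scores, y)
  s <- as.numeric(scores)
  lab <- as.numeric(y) > 0
  npos <- sum(lab)
  if (npos == 0L) stop_po2go("no positive labels", "po2go_metric_error")
  if (npos == length(lab)) return(1)
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  lab <- lab[o]
  # group tied scores into single PR points
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(lab)[grp_end]
  np <- grp_end
  prec <- tp / np
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Information content of terms from propagated annotation counts
#'
#' `IC(t) = -log2(count(t) / n)` with counts taken from the true-path-closed
#' annotation matrix. Terms never observed receive the IC of the rarest
#' observed term; terms annotated to every protein (the roots, typically)
#' get 0.
#'
#' @param y True-path-closed binary annotation matrix (proteins x terms).
#' @param base Logarithm base (default 2).
#' @return Named numeric vector of per-term IC.
#' @export
information_content <- function(y, base = 2) {
  if (nrow(y) == 0L || sum(y) == 0) {
    stop_po2go("empty annotation matrix", "po2go_metric_error")
  }
  counts <- colSums(y > 0)
  freq <- counts / nrow(y)
  ic <- -log(freq, base = base)
  if (any(counts == 0L)) {
    ic[counts == 0L] <- max(ic[counts > 0L])
  }
  ic
}

#' Average information content of true-positive predictions
#'
#' Per protein, the mean IC of terms that are both predicted at or above the
#' threshold and true; averaged over proteins that have at least one true
#' positive. The threshold is typically the Fmax-maximizing one.
#'
#' @inheritParams s_min
#' @param threshold Score threshold.
#' @return Scalar, or `NA` when no protein has a true positive.
#' @export
avg_ic_true_positives <- function(scores, y, ic, threshold) {
  check_scores(scores, y)
  icv <- as.numeric(ic[colnames(y)])
  pred <- scores >= threshold
  tp <- pred & (y == 1)
  per_protein <- vapply(seq_len(nrow(y)), function(i) {
    sel <- tp[i, ]
    if (!any(sel)) NA_real_ else mean(icv[sel])
  }, numeric(1))
  if (all(is.na(per_protein))) return(NA_real_)
  mean(per_protein, na.rm = TRUE)
}

#' Term-centric F1 by annotation-count group
#'
#' Groups terms by how many proteins they annotate, computes the per-term
#' binary F1 at the given threshold and averages within each group — the
#' few-shot view of predictor performance.
#'
#' @inheritParams f_max
#' @param bins Lower bin edges over annotation counts; default
#'   `c(1, 11, 31, 101, 301)` meaning 1-10, 11-30, 31-100, 101-300, >300.
#' @param threshold Score threshold (typically the Fmax one).
#' @return Tibble with columns `bin`, `n_terms`, `f1`; empty bins are absent.
#' @export
term_centric_f1_by_group <- function(scores, y, threshold,
                                     bins = c(1, 11, 31, 101, 301)) {
  check_scores(scores, y)
  counts <- colSums(y > 0)
  keep <- counts >= 1
  if (!any(keep)) stop_po2go("no annotated terms", "po2go_metric_error")
  pred <- scores >= threshold
  f1 <- vapply(which(keep), function(j) {
    tp <- sum(pred[, j] & y[, j] == 1)
    fp <- sum(pred[, j] & y[, j] == 0)
    fn <- sum(!pred[, j] & y[, j] == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  edges <- c(bins, Inf)
  labels <- vapply(seq_along(bins), function(b) {
    if (is.infinite(edges[[b + 1]])) sprintf(">=%d", bins[[b]])
    else sprintf("%d-%d", bins[[b]], edges[[b + 1]] - 1)
  }, character(1))
  grp <- cut(counts[keep], breaks = c(bins - 0.5, Inf), labels = labels)
  out <- tibble::tibble(bin = grp, f1 = f1) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_terms = dplyr::n(), f1 = mean(.data$f1), .groups = "drop")
  out$bin <- as.character(out$bin)
  out[, c("bin", "n_terms", "f1")]
}
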