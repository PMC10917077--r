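#' Build the per-term neighbor index
#'
#' For every non-obsolete term `t` the index holds three pairwise-disjoint
#' lists: `Q_dr(t)` — directly reachable terms (ancestors and descendants),
#' `Q_ir(t)` — indirectly reachable terms (joined only through a common
#' ancestor), each sorted ascending by SRP length; and `Q_ur(t)` — the terms
#' of other domains. Together the three lists partition all other terms when
#' every domain is connected.
#'
#' @param dag An [ontology_dag].
#' @return An object of class `po2go_index` with elements `term_ids`,
#'   `domains`, `srp` (the all-pairs SRP length matrix), and per-term integer
#'   index vectors `dr`, `ir`, `ur` plus matching SRP lengths `dr_len`,
#'   `ir_len` and positive-candidate vectors `pos`.
#' @export
build_index <- function(dag) {
  ids <- active_terms(dag)
  S <- srp_matrix(dag)
  domains <- dag$terms$domain[match(ids, dag$terms$term_id)]
  m <- length(ids)
  dr <- ir <- ur <- pos <- vector("list", m)
  dr_len <- ir_len <- vector("list", m)
  for (i in seq_len(m)) {
    s <- S[i, ]
    s[i] <- NA_real_ # exclude self
    is_dr <- which(is.finite(s) & s %% 1 == 0)
    is_ir <- which(is.finite(s) & s %% 1 == 0.5)
    is_ur <- which(!is.na(s) & !is.finite(s))
    odr <- is_dr[order(s[is_dr])]
    oir <- is_ir[order(s[is_ir])]
    dr[[i]] <- odr
    dr_len[[i]] <- unname(s[odr])
    ir[[i]] <- oir
    ir_len[[i]] <- unname(s[oir])
    ur[[i]] <- is_ur
    pos[[i]] <- c(odr[s[odr] == 1], oir[s[oir] == 2.5])
  }
  structure(
    list(term_ids = ids, domains = domains, srp = S,
         dr = dr, ir = ir, ur = ur, dr_len = dr_len, ir_len = ir_len,
         pos = pos),
    class = "po2go_index"
  )
}

#' @export
print.po2go_index <- function(x, ...) {
  cat(sprintf("<po2go_index> %d terms, %d domain(s)\n",
              length(x$term_ids), length(unique(x$domains))))
  invisible(x)
}

index_pos <- function(index, term) {
  i <- match(term, index$term_ids)
  if (is.na(i)) stop_po2go(sprintf("unknown term id: %s", term), "po2go_lookup_error")
  i
}

#' Sampler configuration
#'
#' @param k Total number of negative samples per anchor (>= 3).
#' @param u Fraction cap, in (0,1), for the directly-reachable negative class.
#' @param seed Integer seed for the sampling stream.
#' @return A list of class `po2go_sampler_config`.
#' @export
sampler_config <- function(k = 64L, u = 0.5, seed = 1L) {
  stopifnot(is_count(k), k >= 3, is.numeric(u), u > 0, u < 1)
  structure(list(k = as.integer(k), u = u, seed = as.integer(seed)),
            class = "po2go_sampler_config")
}

#' Sample a positive partner for an anchor term
#'
#' Positives are the closest relatives: directly reachable terms at SRP
#' length 1 (parents or children) or indirectly reachable terms at SRP
#' length 2.5 (siblings). The draw is uniform over the union of the two
#' candidate classes and uses the ambient RNG state.
#'
#' @param index A [build_index()] result.
#' @param term Anchor term id.
#' @return A term id.
#' @export
sample_positive <- function(index, term) {
  i <- index_pos(index, term)
  cand <- index$pos[[i]]
  if (length(cand) == 0L) {
    stop_po2go(sprintf("term %s has no positive candidates (isolated term)", term),
               "po2go_sampling_error")
  }
  index$term_ids[resample(cand, 1L)]
}

#' Stratified negative sampling
#'
#' Draws `k` negatives split over the three reachability classes. The direct
#' class gets `min(floor(k*u), |eligible Q_dr|)` draws, the indirect class
#' `min(floor((k - |N_dr|)/2), |eligible Q_ir|)`, and the unreachable class
#' the remainder; eligibility in the first two classes means SRP length
#' strictly greater than `srp(term, positive)` so every negative is farther
#' from the anchor than the positive. Deficits spill toward `Q_ur`, and back
#' to `Q_ir`/`Q_dr` when `Q_ur` is short; if the union of eligible pools
#' holds fewer than `k` terms, all of them are returned and the result
#' carries a `short` attribute (with a warning).
#'
#' Sampling is without replacement within each list and uses the ambient RNG.
#'
#' @param index A [build_index()] result.
#' @param term Anchor term id.
#' @param positive The sampled positive term id for this anchor.
#' @param cfg A [sampler_config()].
#' @return A list with character vectors `N_dr`, `N_ir`, `N_ur`; attribute
#'   `short = TRUE` when fewer than `k` eligible negatives existed.
#' @export
sample_negatives <- function(index, term, positive, cfg) {
  i <- index_pos(index, term)
  j <- index_pos(index, positive)
  s_pos <- index$srp[i, j]
  if (!(s_pos %in% c(1, 2.5))) {
    stop_po2go(sprintf("positive %s is not a valid positive for %s (srp %s)",
                       positive, term, format(s_pos)), "po2go_sampling_error")
  }
  k <- cfg$k
  # dr_len/ir_len are sorted ascending: eligible candidates form a suffix
  edr <- index$dr[[i]][index$dr_len[[i]] > s_pos]
  eir <- index$ir[[i]][index$ir_len[[i]] > s_pos]
  eur <- index$ur[[i]]

  n_dr <- min(floor(k * cfg$u), length(edr))
  n_ir <- min(floor((k - n_dr) / 2), length(eir))
  n_ur <- min(k - n_dr - n_ir, length(eur))
  # spill any unreachable-pool deficit back to the graded classes
  deficit <- k - n_dr - n_ir - n_ur
  if (deficit > 0L) {
    add_ir <- min(deficit, length(eir) - n_ir)
    n_ir <- n_ir + add_ir
    deficit <- deficit - add_ir
  }
  if (deficit > 0L) {
    add_dr <- min(deficit, length(edr) - n_dr)
    n_dr <- n_dr + add_dr
    deficit <- deficit - add_dr
  }
  out <- list(
    N_dr = index$term_ids[resample(edr, n_dr)],
    N_ir = index$term_ids[resample(eir, n_ir)],
    N_ur = index$term_ids[resample(eur, n_ur)]
  )
  if (deficit > 0L) {
    warn(sprintf("term %s: only %d eligible negatives for k = %d",
                 term, k - deficit, k))
    attr(out, "short") <- TRUE
  }
  out
}
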