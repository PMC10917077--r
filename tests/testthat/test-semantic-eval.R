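test_that("cosine matches the brute-force formula and rejects zero vectors", {
  expect_equal(cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  withr::with_seed(5L, {
    for (i in 1:5) {
      a <- rnorm(6); b <- rnorm(6)
      expect_equal(cosine(a, b), sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    }
  })
  expect_error(cosine(c(0, 0), c(1, 1)), class = "po2go_undefined_similarity")
  expect_error(cosine(c(1, 2), c(1, 2, 3)), class = "po2go_shape_error")
})

test_that("wasserstein_1 matches closed forms and the matching oracle", {
  expect_equal(wasserstein_1(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1(5, 2), 3) # point masses
  withr::with_seed(8L, {
    for (i in 1:10) {
      a <- rnorm(6); b <- rnorm(6)
      expect_equal(wasserstein_1(a, b), oracle_wasserstein_matching(a, b))
    }
    # unequal sizes: CDF-integral route, cross-checked with a closed case
    expect_equal(wasserstein_1(c(0, 1), c(0.5)), 0.5)
    # metric properties on equal-size samples
    for (i in 1:10) {
      a <- rnorm(5); b <- rnorm(5); c <- rnorm(5)
      expect_equal(wasserstein_1(a, b), wasserstein_1(b, a))
      expect_lte(wasserstein_1(a, c),
                 wasserstein_1(a, b) + wasserstein_1(b, c) + 1e-12)
    }
  })
  expect_error(wasserstein_1(numeric(), 1), class = "po2go_size_error")
})

test_that("ancestor similarity separates for trained embeddings, not random", {
  dag <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 25L,
                               multi_parent_prob = 0.2, seed = 1L))
  fit <- train_embeddings(dag,
                          train_config(tau = 0.1, d_prime = 8L, epochs = 60L,
                                       learning_rate = 0.01, seed = 1L),
                          sampler_config(k = 8L, u = 0.5, seed = 2L))
  d_tr <- ancestor_similarity_distributions(dag, fit$embedding, 150L, seed = 3L)
  expect_equal(length(d_tr$ancestor$values), 150L)
  expect_gt(median(d_tr$ancestor$values), median(d_tr$non_ancestor$values))
  d_rnd <- ancestor_similarity_distributions(dag, random_embeddings(dag, 8L, 1L),
                                             150L, seed = 3L)
  expect_gt(wasserstein_1(d_tr$ancestor, d_tr$non_ancestor),
            wasserstein_1(d_rnd$ancestor, d_rnd$non_ancestor))
  # random embeddings carry no structure: distance near zero
  expect_lt(wasserstein_1(d_rnd$ancestor, d_rnd$non_ancestor), 0.05)
})

test_that("depth probe reads depth from informative features, not noise", {
  dag <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 40L,
                               multi_parent_prob = 0.2, seed = 2L))
  depths <- term_depths(dag)
  ids <- active_terms(dag)
  # toy depth-revealing feature: depth itself plus small jitter
  X <- withr::with_seed(4L,
    cbind(depths[ids] + rnorm(length(ids), sd = 0.01),
          matrix(rnorm(length(ids) * 3L), ncol = 3L)))
  rownames(X) <- ids
  rep_toy <- depth_probe(embedding_table(X), depths, split_seed = 5L)
  expect_lt(rep_toy$mse, 0.5)
  expect_gt(rep_toy$spearman, 0.9)
  # constant depths: probe degenerates gracefully
  const <- stats::setNames(rep(3L, length(ids)), ids)
  rep_const <- depth_probe(embedding_table(X), const, split_seed = 5L)
  expect_equal(rep_const$mse, 0)
  expect_true(is.na(rep_const$spearman))
  # deterministic given the seed
  rep2 <- depth_probe(embedding_table(X), depths, split_seed = 5L)
  expect_identical(rep_toy, rep2)
})

test_that("BMA similarity is symmetric, bounded, and matches the double loop", {
  E <- withr::with_seed(6L,
    matrix(rnorm(40), 10, 4, dimnames = list(paste0("T", 1:10), NULL)))
  emb <- embedding_table(E)
  A <- c("T1", "T2", "T3")
  B <- c("T4", "T5", "T6")
  got <- bma_similarity(A, B, emb)
  # brute-force double loop
  cs <- function(a, b) cosine(E[a, ], E[b, ])
  best_ab <- vapply(A, function(a) max(vapply(B, cs, numeric(1), a = a)), numeric(1))
  best_ba <- vapply(B, function(b) max(vapply(A, function(a) cs(a, b), numeric(1))),
                    numeric(1))
  expect_equal(got, (mean(best_ab) + mean(best_ba)) / 2)
  expect_equal(got, bma_similarity(B, A, emb))
  expect_lte(abs(got), 1)
  expect_equal(bma_similarity(A, A, emb), 1)
  expect_error(bma_similarity(character(), B, emb),
               class = "po2go_annotation_error")
})

test_that("correlation_report matches textbook formulas and closed cases", {
  x <- c(2, 4, 1, 7, 5, 9, 3, 8, 6, 10)
  y <- 2 * x + 1
  r <- correlation_report(x, y)
  expect_equal(r$pearson, 1)
  expect_equal(r$spearman, 1)
  expect_equal(correlation_report(sort(x), rev(sort(x)))$spearman, -1)
  withr::with_seed(7L, {
    a <- rnorm(10); b <- rnorm(10)
    rr <- correlation_report(a, b)
    # product-moment by hand
    expect_equal(rr$pearson,
                 sum((a - mean(a)) * (b - mean(b))) /
                   sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
    expect_equal(rr$spearman, cor(rank(a), rank(b)))
  })
  expect_error(correlation_report(rep(1, 5), 1:5),
               class = "po2go_degenerate_correlation")
})

test_that("domain separation scores clean clusters high and permuted labels near 0", {
  withr::with_seed(9L, {
    E <- rbind(matrix(rnorm(40, mean = 5), 20, 2),
               matrix(rnorm(40, mean = -5), 20, 2))
    rownames(E) <- paste0("T", 1:40)
    doms <- stats::setNames(rep(c("a", "b"), each = 20), rownames(E))
    expect_gt(domain_separation(embedding_table(E), doms), 0.8)
    perm <- stats::setNames(sample(doms), names(doms))
    expect_lt(abs(domain_separation(embedding_table(E), perm)), 0.15)
  })
  expect_error(domain_separation(embedding_table(
    matrix(1:4, 2, 2, dimnames = list(c("T1", "T2"), NULL)) * 1.0),
    c(T1 = "a", T2 = "a")), class = "po2go_config_error")
})

test_that("2-d projection hook emits coordinates for every term", {
  E <- withr::with_seed(2L,
    matrix(rnorm(60), 15, 4, dimnames = list(paste0("T", 1:15), NULL)))
  pr <- project_2d(embedding_table(E),
                   stats::setNames(rep(c("a", "b", "c"), 5), rownames(E)))
  expect_named(pr, c("term_id", "x", "y", "domain"))
  expect_equal(nrow(pr), 15L)
})
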