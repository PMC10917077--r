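test_that("the fixture ontology reproduces every printed SRP case", {
  dag <- fig2_fixture()
  expect_equal(srp(dag, "GO:0043227", "GO:0110165")$length, 2)
  expect_equal(srp(dag, "GO:0043227", "GO:1990900")$length, 3.5)
  expect_equal(srp(dag, "GO:0043227", "GO:0044238")$length, Inf)
})

test_that("generated DAGs satisfy the structural invariants at any spec", {
  specs <- list(
    dag_spec(domains = 1L, terms_per_domain = 1L, depth_target = 1L, seed = 0L),
    dag_spec(domains = 1L, terms_per_domain = 25L, multi_parent_prob = 0, seed = 1L),
    dag_spec(domains = 3L, terms_per_domain = 15L, multi_parent_prob = 0.4, seed = 2L)
  )
  for (spec in specs) {
    dag <- generate_dag(spec) # ontology_dag() validates acyclicity/roots
    expect_s3_class(dag, "po2go_dag")
    expect_equal(length(dag$roots), spec$domains)
    expect_gte(nrow(dag$edges), nrow(dag$terms) - spec$domains)
    # connectivity: every term reaches its domain root
    for (t in active_terms(dag)) {
      dom <- dag$terms$domain[[match(t, dag$terms$term_id)]]
      expect_true(t == dag$roots[[dom]] ||
                    dag$roots[[dom]] %in% ancestors_of(dag, t))
    }
    expect_true(all(term_depths(dag) <= spec$depth_target))
  }
  # multi-parent probability adds edges beyond the tree
  dag_mp <- generate_dag(dag_spec(domains = 1L, terms_per_domain = 40L,
                                  multi_parent_prob = 0.5, seed = 0L))
  expect_gt(nrow(dag_mp$edges), 39L)
  expect_error(generate_dag(dag_spec(terms_per_domain = 3L, depth_target = 9L)),
               class = "po2go_spec_error")
})

test_that("generators are pure functions of spec and seed", {
  s <- dag_spec(domains = 2L, terms_per_domain = 20L, seed = 7L)
  expect_identical(generate_dag(s)$edges, generate_dag(s)$edges)
  dag <- generate_dag(s)
  a <- annotation_spec(n_proteins = 20L, seed = 8L)
  expect_identical(generate_annotations(dag, a), generate_annotations(dag, a))
  y <- generate_annotations(dag, a)
  v <- signal_spec(d = 8L, noise_sd = 0.2, seed = 9L)
  expect_identical(generate_protein_vectors(y, v), generate_protein_vectors(y, v))
  expect_identical(generate_pair_benchmark(y, "pfam_like", seed = 10L),
                   generate_pair_benchmark(y, "pfam_like", seed = 10L))
})

test_that("annotations are true-path fixed points with the requested size", {
  dag <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 20L, seed = 1L))
  y <- generate_annotations(dag, annotation_spec(n_proteins = 30L, seed = 2L))
  expect_equal(nrow(y), 30L)
  expect_identical(propagate_true_path(y, dag), y)
  expect_true(all(rowSums(y) >= 1))
})

test_that("leaf_bias 0 draws direct terms uniformly", {
  dag <- generate_dag(dag_spec(domains = 1L, terms_per_domain = 10L, seed = 3L))
  # direct draws are latent after propagation; test the weighting itself via
  # a chi-square on many single-term proteins drawn at leaf_bias 0
  y <- generate_annotations(dag, annotation_spec(n_proteins = 5000L,
                                                 leaf_bias = 0,
                                                 terms_per_protein = 1,
                                                 seed = 4L))
  # each protein drew exactly one direct term, uniform over the 10 terms;
  # recover it as the deepest annotated term of the protein's closure is
  # not unique, so instead count closures: expected closure count for term t
  # is n/10 * |descendants(t) + self|
  counts <- colSums(y)
  expected <- vapply(active_terms(dag), function(t) {
    5000 / 10 * (1 + length(descendants_of(dag, t)))
  }, numeric(1))
  chisq <- sum((counts - expected)^2 / expected)
  # 9 df; 0.999 quantile ~ 27.9
  expect_lt(chisq, 30)
})

test_that("protein vectors carry exact signal at zero noise", {
  dag <- generate_dag(dag_spec(domains = 1L, terms_per_domain = 12L, seed = 5L))
  y <- generate_annotations(dag, annotation_spec(n_proteins = 20L, seed = 6L))
  spec <- signal_spec(d = 8L, noise_sd = 0, seed = 7L)
  P <- generate_protein_vectors(y, spec)
  # identical annotation closures give identical vectors
  key <- apply(y, 1, paste, collapse = "")
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup) >= 2L) {
    pair <- dup[key[dup] == key[dup[1]]][1:2]
    expect_equal(P[pair[1], ], P[pair[2], ])
  }
  # single-term proteins equal that term's loading row: reconstruct loadings
  L <- withr::with_seed(spec$seed, matrix(rnorm(ncol(y) * spec$d), ncol(y), spec$d))
  i <- which(rowSums(y) == min(rowSums(y)))[1]
  expect_equal(unname(P[i, ]),
               unname(colMeans(L[y[i, ] > 0, , drop = FALSE])))
})

test_that("pair benchmarks score Jaccard overlap of true annotation sets", {
  y <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0,
                0, 0, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(paste0("P", 1:3), paste0("G", 1:4)))
  b <- generate_pair_benchmark(y, "pfam_like", n_pairs = 50L, seed = 1L)
  same <- b$protein_a %in% c("P1", "P2") & b$protein_b %in% c("P1", "P2")
  expect_true(all(b$target[same] == 1)) # identical sets
  cross <- xor(b$protein_a == "P3", b$protein_b == "P3")
  expect_true(all(b$target[cross] == 0)) # disjoint sets
  bin <- generate_pair_benchmark(y, "ppi_like", n_pairs = 50L, seed = 1L)
  expect_true(all(bin$target %in% c(0, 1)))
  expect_error(generate_pair_benchmark(y[1, , drop = FALSE], "pfam_like"),
               class = "po2go_size_error")
})

test_that("BMA on trained embeddings correlates with the Jaccard benchmark", {
  dag <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 25L, seed = 1L))
  fit <- train_embeddings(dag,
                          train_config(tau = 0.1, d_prime = 8L, epochs = 60L,
                                       learning_rate = 0.01, seed = 1L),
                          sampler_config(k = 8L, u = 0.5, seed = 2L))
  y <- generate_annotations(dag, annotation_spec(n_proteins = 40L, seed = 3L))
  bench <- generate_pair_benchmark(y, "pfam_like", n_pairs = 120L, seed = 4L)
  sets <- attr(bench, "annotations")
  sem <- vapply(seq_len(nrow(bench)), function(i) {
    bma_similarity(sets[[bench$protein_a[[i]]]], sets[[bench$protein_b[[i]]]],
                   fit$embedding)
  }, numeric(1))
  r <- correlation_report(sem, bench$target)
  expect_gt(r$pearson, 0)
})
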