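test_that("parse_obo keeps only is_a/part_of, drops other relationship types", {
  obo <- c(
    "[Term]", "id: X:1", "name: root", "namespace: d", "",
    "[Term]", "id: X:2", "name: a", "namespace: d", "is_a: X:1", "",
    "[Term]", "id: X:3", "name: b", "namespace: d",
    "relationship: part_of X:1", "relationship: regulates X:2", "",
    "[Term]", "id: X:4", "name: c", "namespace: d", "is_a: X:2",
    "alt_id: X:9", ""
  )
  dag <- parse_obo(obo)
  expect_equal(nrow(dag$terms), 4L)
  expect_equal(nrow(dag$edges), 3L) # regulates dropped
  expect_setequal(dag$edges$relation, c("is_a", "part_of"))
  expect_equal(unname(dag$roots), "X:1")
  expect_equal(resolve_term_ids(dag, "X:9"), "X:4")
})

test_that("parse_obo handles the printed three-term chain and one-term files", {
  chain <- c("[Term]", "id: GO:0110165", "namespace: cc", "",
             "[Term]", "id: GO:0043226", "namespace: cc", "is_a: GO:0110165", "",
             "[Term]", "id: GO:0043227", "namespace: cc", "is_a: GO:0043226")
  dag <- parse_obo(chain)
  expect_equal(nrow(dag$terms), 3L)
  expect_equal(nrow(dag$edges), 2L)

  single <- c("[Term]", "id: GO:1", "namespace: cc")
  one <- parse_obo(single)
  expect_equal(nrow(one$terms), 1L)
  expect_equal(nrow(one$edges), 0L)
  expect_equal(unname(one$roots), "GO:1")
})

test_that("parse_obo rejects malformed stanzas naming the line, and cycles", {
  expect_error(parse_obo(c("[Term]", "id: A:1", "not a key value")),
               "line 3", class = "po2go_parse_error")
  cyc <- c("[Term]", "id: A:1", "namespace: d", "is_a: A:2", "",
           "[Term]", "id: A:2", "namespace: d", "is_a: A:1")
  expect_error(parse_obo(cyc), class = "po2go_structure_error")
})

test_that("obsolete terms are retained as records but carry no edges", {
  obo <- c("[Term]", "id: A:1", "namespace: d", "",
           "[Term]", "id: A:2", "namespace: d", "is_a: A:1", "",
           "[Term]", "id: A:3", "namespace: d", "is_obsolete: true")
  dag <- parse_obo(obo)
  expect_true("A:3" %in% dag$terms$term_id)
  expect_false("A:3" %in% active_terms(dag))
  expect_false("A:3" %in% c(dag$edges$child, dag$edges$parent))
  expect_error(srp(dag, "A:1", "A:3"), class = "po2go_lookup_error")
})

test_that("ancestors match the printed example and a repeated-expansion oracle", {
  dag <- fig2_fixture()
  expect_setequal(ancestors_of(dag, "GO:0043227"),
                  c("GO:0043226", "GO:0110165"))
  expect_length(ancestors_of(dag, "GO:0110165"), 0L) # domain root
  expect_error(ancestors_of(dag, "GO:9999999"), class = "po2go_lookup_error")

  big <- generate_dag(dag_spec(domains = 1L, terms_per_domain = 30L,
                               multi_parent_prob = 0.3, seed = 5L))
  for (t in sample(active_terms(big), 8L)) {
    expect_setequal(ancestors_of(big, t), oracle_ancestors(big$edges, t))
  }
})

test_that("srp reproduces all printed worked cases on the mini ontology", {
  dag <- fig2_fixture()
  expect_equal(srp(dag, "GO:0043227", "GO:0110165"),
               list(length = 2, reachability = "direct"))
  expect_equal(srp(dag, "GO:0043227", "GO:0043226"),
               list(length = 1, reachability = "direct"))
  expect_equal(srp(dag, "GO:0043227", "GO:0043229"),
               list(length = 2.5, reachability = "indirect"))
  expect_equal(srp(dag, "GO:0043227", "GO:1990900"),
               list(length = 3.5, reachability = "indirect"))
  expect_equal(srp(dag, "GO:0043227", "GO:0044238")$length, Inf)
  expect_equal(srp(dag, "GO:0043227", "GO:0043227"),
               list(length = 0, reachability = "direct"))
})

test_that("srp and srp_matrix agree with the BFS/common-ancestor oracle", {
  dag <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 15L,
                               multi_parent_prob = 0.25, seed = 3L))
  ids <- active_terms(dag)
  S <- srp_matrix(dag)
  O <- oracle_srp_matrix(dag)
  expect_equal(S, O)
  # spot-check the single-pair path against the matrix
  for (p in list(c(1, 5), c(2, 20), c(7, 29))) {
    r <- srp(dag, ids[[p[1]]], ids[[p[2]]])
    expect_equal(r$length, S[p[1], p[2]])
  }
})

test_that("srp is symmetric and partitions pairs by domain connectivity", {
  dag <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 15L,
                               multi_parent_prob = 0.2, seed = 9L))
  S <- srp_matrix(dag)
  expect_equal(S, t(S))
  ids <- active_terms(dag)
  dom <- dag$terms$domain[match(ids, dag$terms$term_id)]
  same <- outer(dom, dom, "==")
  off <- upper.tri(S)
  expect_true(all(is.finite(S[off & same]))) # connected domain: never unreachable
  expect_true(all(!is.finite(S[off & !same]))) # cross-domain: always unreachable
})

test_that("term depth is the longest root path", {
  dag <- fig2_fixture()
  expect_equal(term_depth(dag, "GO:0043227"), 2L)
  expect_equal(term_depth(dag, "GO:0110165"), 0L)
  # diamond with a long and a short route: longest wins
  terms <- data.frame(term_id = c("R", "A", "B", "C"), domain = "d")
  edges <- data.frame(child = c("A", "B", "C", "C"),
                      parent = c("R", "A", "B", "R"),
                      relation = "is_a")
  dd <- ontology_dag(terms, edges)
  expect_equal(term_depth(dd, "C"), 3L)
  # every child is at least one deeper than each parent
  big <- generate_dag(dag_spec(domains = 1L, terms_per_domain = 40L,
                               multi_parent_prob = 0.3, seed = 2L))
  dep <- term_depths(big)
  expect_true(all(dep[big$edges$child] >= dep[big$edges$parent] + 1L))
})

test_that("true path propagation matches the printed example and the oracle", {
  dag <- fig2_fixture()
  y <- matrix(1L, 1, 1, dimnames = list("P1", "GO:0043227"))
  out <- propagate_true_path(y, dag)
  expect_setequal(colnames(out)[out["P1", ] == 1],
                  c("GO:0043227", "GO:0043226", "GO:0110165"))
  # roots only: unchanged annotation set
  yr <- matrix(1L, 1, 2, dimnames = list("P1", c("GO:0110165", "GO:0044238")))
  outr <- propagate_true_path(yr, dag)
  expect_equal(sum(outr), 2L)
  # idempotence and oracle equality on random synthetic annotations
  big <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 20L, seed = 4L))
  ann <- generate_annotations(big, annotation_spec(n_proteins = 15L, seed = 6L))
  expect_equal(propagate_true_path(ann, big), ann) # already closed
  raw <- ann
  raw[, ] <- 0L
  raw[cbind(1:15, sample(ncol(ann), 15L))] <- 1L
  closed <- propagate_true_path(raw, big)
  expect_equal(closed, oracle_propagate(raw, big))
  expect_equal(propagate_true_path(closed, big), closed)
  expect_true(all(closed >= raw))
  # unknown term named in the error
  bad <- matrix(1L, 1, 1, dimnames = list("P9", "NO:0000001"))
  expect_error(propagate_true_path(bad, big), "NO:0000001",
               class = "po2go_lookup_error")
})

test_that("annotation readers accept GAF and two-column TSV", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("P1\tGO:0043227", "P2\tGO:0043226"), tsv)
  ann <- read_annotation_pairs(tsv)
  expect_equal(nrow(ann), 2L)
  expect_named(ann, c("protein_id", "term_id"))

  gaf <- tempfile(fileext = ".gaf")
  row <- function(p, t, ev) paste(c("UniProt", p, p, "", t, "PMID:1", ev,
                                    "", "C", "", "", "protein", "taxon:9606",
                                    "20200101", "UniProt"), collapse = "\t")
  writeLines(c("!gaf-version: 2.1", row("P1", "GO:0043227", "EXP"),
               row("P2", "GO:0043226", "IEA")), gaf)
  all_rows <- read_annotation_pairs(gaf)
  expect_equal(nrow(all_rows), 2L)
  exp_only <- read_annotation_pairs(gaf, evidence = "EXP")
  expect_equal(exp_only$protein_id, "P1")
})

test_that("write_obo / parse_obo round-trips a generated ontology", {
  dag <- generate_dag(dag_spec(domains = 2L, terms_per_domain = 12L,
                               multi_parent_prob = 0.3, seed = 8L))
  path <- tempfile(fileext = ".obo")
  write_obo(dag, path)
  back <- parse_obo(path)
  expect_equal(back$terms$term_id, dag$terms$term_id)
  expect_equal(
    dplyr::arrange(back$edges, child, parent),
    dplyr::arrange(dag$edges, child, parent)
  )
  expect_equal(srp_matrix(back), srp_matrix(dag))
})
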