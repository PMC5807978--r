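# Ontology handling, dual-level enrichment, Wang similarity.

diamond_dag <- function() {
  # root <- b1, b2 <- leaf (two parents)
  ontology_dag(data.frame(child = c("b1", "b2", "leaf", "leaf"),
                          parent = c("root", "root", "b1", "b2")))
}

test_that("ontology construction validates rootedness and acyclicity", {
  expect_s3_class(chain_dag(3), "ontology_dag")
  expect_error(ontology_dag(data.frame(child = c("a", "b"),
                                       parent = c("b", "a"))),
               "root")
  expect_error(ontology_dag(data.frame(child = c("a", "b", "c"),
                                       parent = c("r1", "r2", "a"))),
               "exactly one root")
  # a cycle below a root is caught
  expect_error(ontology_dag(data.frame(child = c("a", "b", "c", "b"),
                                       parent = c("root", "a", "b", "c"))),
               "cycle")
})

test_that("ancestor propagation is correct on chains and diamonds, and idempotent", {
  dag <- chain_dag(2)   # root -> n1 -> n2
  direct <- data.frame(gene_id = "g1", category = "n2")
  prop <- propagate_ancestors(direct, dag)
  expect_setequal(prop$category, c("n2", "n1", "root"))
  # annotation at the root only: unchanged
  at_root <- data.frame(gene_id = "g1", category = "root")
  expect_equal(propagate_ancestors(at_root, dag), at_root)
  # diamond: union of ancestors, no duplicates
  dd <- diamond_dag()
  pd <- propagate_ancestors(data.frame(gene_id = "g", category = "leaf"), dd)
  expect_setequal(pd$category, c("leaf", "b1", "b2", "root"))
  expect_equal(anyDuplicated(pd), 0)
  # idempotence
  expect_setequal(propagate_ancestors(pd, dd)$category, pd$category)
  expect_error(propagate_ancestors(
    data.frame(gene_id = "g", category = "nope"), dd), "unknown")
})

test_that("depth filter retains the mid-depth band", {
  dag <- chain_dag(6)
  d <- dag_depths(dag)
  expect_equal(unname(d$longest[c("root", "n1", "n6")]), c(0, 1, 6))
  # in a chain both path lengths coincide: keep depths 3 and 4
  expect_setequal(depth_filter(dag), c("n3", "n4"))
  expect_false("root" %in% depth_filter(dag))
  # node with parents at depths 1 and 4: longest 5, shortest 2 -> retained
  edges <- rbind(
    data.frame(child = paste0("c", 1:4),
               parent = c("root", "c1", "c2", "c3")),
    data.frame(child = "x", parent = c("c1", "c4")))
  dag2 <- ontology_dag(edges)
  d2 <- dag_depths(dag2)
  expect_equal(unname(d2$longest["x"]), 5)
  expect_equal(unname(d2$shortest["x"]), 2)
  expect_true("x" %in% depth_filter(dag2))
})

test_that("depth filter is stable under leaves added below retained nodes", {
  dag <- chain_dag(6)
  kept <- depth_filter(dag)
  edges2 <- rbind(dag$edges, data.frame(child = "extra", parent = "n6"))
  expect_setequal(intersect(depth_filter(ontology_dag(edges2)), dag$nodes),
                  kept)
})

test_that("OBO subset round-trips through the parser", {
  dag <- diamond_dag()
  dag$term_names <- stats::setNames(paste("term", dag$nodes), dag$nodes)
  tmp <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, tmp)
  back <- read_obo(tmp)
  expect_setequal(back$nodes, dag$nodes)
  expect_equal(back$root, "root")
  expect_setequal(paste(back$edges$child, back$edges$parent),
                  paste(dag$edges$child, dag$edges$parent))
  expect_equal(unname(back$term_names["leaf"]), "term leaf")
})

test_that("gene-level hypergeometric p matches exhaustive enumeration", {
  universe <- sprintf("g%02d", 1:10)
  category <- list(cat = universe[1:4])
  cluster <- universe[1:5]          # overlap 4
  res <- gene_level_test(cluster, category, universe)
  # oracle: enumerate all C(10,5) draws, count those with >= 4 of the 4
  draws <- combn(10, 5)
  hits <- sum(apply(draws, 2, function(d) sum(d <= 4) >= 4))
  expect_equal(res$p, hits / ncol(draws))
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  # category equal to the universe: p = 1
  res2 <- gene_level_test(cluster, list(all = universe), universe)
  expect_equal(res2$p, 1)
  # zero overlap with positive expectation: p near 1, from the exact CDF
  res3 <- gene_level_test(universe[6:10], category, universe)
  expect_equal(res3$overlap, 0)
  expect_equal(res3$p, 1)
})

test_that("weighted resampling reduces to the hypergeometric under uniform weights", {
  universe <- sprintf("t%02d", 1:10)
  lengths <- stats::setNames(rep(1000, 10), universe)  # degenerate -> uniform
  category <- list(cat = universe[1:4])
  cluster <- universe[1:5]
  expect_message(
    res <- transcript_level_test(cluster, category, universe, lengths,
                                 n_resamples = 10000, seed = 8),
    "uniform-weight")
  expect_lt(abs(res$p - 6 / 252), 0.01)
  # empty category: p = 1
  res0 <- transcript_level_test(cluster, list(none = character(0)),
                                universe, lengths, n_resamples = 100, seed = 1)
  expect_equal(res0$p, 1)
})

test_that("length-aware weighting penalises length-driven overlap", {
  set.seed(9)
  n <- 400
  universe <- sprintf("t%03d", 1:n)
  lengths <- stats::setNames(sort(round(exp(rnorm(n, log(2000), 0.6)))),
                             universe)
  # cluster = the longest decile: purely length-driven
  cluster <- universe[(n - 39):n]
  category <- list(cat = universe[(n - 59):n])   # long transcripts too
  p_weighted <- transcript_level_test(cluster, category, universe, lengths,
                                      n_resamples = 4000, seed = 10)$p
  p_hyper <- gene_level_test(cluster, category, universe)$p
  expect_gt(p_weighted, p_hyper)
  w <- make_pwf(universe %in% cluster, as.numeric(lengths))
  expect_true(all(diff(w[order(lengths)]) >= -1e-12))   # monotone weights
})

test_that("Wang similarity matches hand-evaluated recursions", {
  dag <- ontology_dag(data.frame(child = "c", parent = "r"))
  expect_equal(wang_similarity("c", "c", dag), 1)
  # S-values of c: {c: 1, r: 0.8}; shared ancestor r only
  expect_equal(wang_similarity("c", "r", dag), 1.8 / 2.8, tolerance = 1e-12)
  dd <- diamond_dag()
  # symmetric in its arguments
  expect_equal(wang_similarity("b1", "b2", dd),
               wang_similarity("b2", "b1", dd))
  # siblings share only the root: sim = (0.8 + 0.8) / (1.8 + 1.8)
  expect_equal(wang_similarity("b1", "b2", dd), 1.6 / 3.6, tolerance = 1e-12)
  # leaf S-values take the max over the two paths to root
  sv <- morphde:::wang_svalues("leaf", dd)
  expect_equal(unname(sv["root"]), 0.64, tolerance = 1e-12)
  expect_true(wang_similarity("leaf", "b1", dd) <= 1)
})

test_that("category clustering matches a brute-force complete-linkage oracle", {
  set.seed(11)
  edges <- data.frame(
    child = c("a", "b", "c", "d", "e"),
    parent = c("root", "root", "a", "a", "b"))
  dag <- ontology_dag(edges)
  cats <- c("a", "b", "c", "d", "e")
  cc <- cluster_categories(cats, dag, cutoff = 0.8)
  expect_equal(unname(diag(cc$similarity)), rep(1, 5))
  expect_equal(cc$similarity, t(cc$similarity))
  # brute-force complete linkage on the same distances
  D <- 1 - cc$similarity
  clusters <- as.list(cats)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(sort(cc$tree$height), sort(heights), tolerance = 1e-12)
  # single category: one cluster
  c1 <- cluster_categories("a", dag)
  expect_equal(unname(c1$super_category), 1L)
  # identical-ancestry categories always co-cluster below cutoff 1
  dag2 <- ontology_dag(data.frame(child = c("p", "x", "y"),
                                  parent = c("root", "p", "p")))
  cc2 <- cluster_categories(c("x", "y"), dag2, cutoff = 0.8)
  expect_equal(cc2$super_category[["x"]], cc2$super_category[["y"]])
})

test_that("dual enrichment flags planted categories and respects the dual rule", {
  truth <- simulate_truth(n_transcripts = 800, n_index_candidates = 0,
                          frac_low = 0, seed = 12)
  ont <- simulate_ontology(truth, seed = 13)
  cluster <- truth$transcript_id[truth$effect_class == "morph"]
  er <- dual_enrichment(cluster, ont, ont$dag, n_resamples = 10000, seed = 14)
  expect_true(all(er$numDE.t <= er$numIn.t))
  expect_true(all(er$numDE.g <= er$numIn.g))
  expect_equal(er$dual_significant, er$fdr.t < 0.01 & er$fdr.g < 0.01)
  expect_true(er$dual_significant[er$category == ont$planted$category])
  # depth filter restricts the tested set
  kept <- depth_filter(ont$dag)
  expect_true(all(er$category %in% kept))
})

test_that("ontology simulation respects planted composition and determinism", {
  truth <- simulate_truth(n_transcripts = 400, n_index_candidates = 0, seed = 15)
  o1 <- simulate_ontology(truth, seed = 16)
  o2 <- simulate_ontology(truth, seed = 16)
  expect_identical(o1$direct, o2$direct)
  expect_identical(o1$dag$edges, o2$dag$edges)
  expect_equal(nrow(o1$planted), 1)
  planted_genes <- o1$direct$gene_id[o1$direct$category == o1$planted$category]
  expect_equal(length(planted_genes), o1$planted$size)
  # planted category enriched in the requested class
  frac_in <- mean(o1$gene_class[planted_genes] == o1$planted$effect_class)
  frac_all <- mean(o1$gene_class == o1$planted$effect_class)
  expect_gt(frac_in, 2 * frac_all)
})
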