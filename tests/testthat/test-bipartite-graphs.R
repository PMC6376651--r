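three_pair_set <- function() {
  association_set(data.frame(
    phenotype_id = c("p1", "p2", "p1"),
    disease_id = c("d1", "d1", "d2"),
    stringsAsFactors = FALSE
  ), disease_labels = c(d1 = "rare", d2 = "common"), provenance = "EMR")
}

test_that("graph construction preserves the pair set over disjoint sides", {
  g <- build_graph(three_pair_set(), name = "fixture")
  expect_equal(length(g$U), 2)
  expect_equal(length(g$V), 2)
  expect_equal(nrow(g$edges), 3)
  expect_setequal(pair_key(g$edges), pair_key(as.data.frame(three_pair_set())))

  empty <- build_graph(association_set(NULL))
  expect_equal(length(empty$U) + length(empty$V) + nrow(empty$edges), 0)

  clash <- data.frame(phenotype_id = c("x", "p"), disease_id = c("d", "x"))
  expect_error(build_graph(association_set(clash)), "both disease and phenotype")
})

test_that("merging graphs unions edges and labels shared edges 'both'", {
  g1 <- build_graph(association_set(
    data.frame(phenotype_id = "p1", disease_id = "d1"), provenance = "KB"), "KB")
  g2 <- build_graph(association_set(
    data.frame(phenotype_id = c("p1", "p2"), disease_id = "d1"),
    provenance = "EMR"), "EMR")
  m <- merge_graphs(g1, g2)
  expect_equal(nrow(m$edges), 2)
  expect_equal(m$edges$provenance[m$edges$phenotype_id == "p1"], "both")
  expect_equal(m$edges$provenance[m$edges$phenotype_id == "p2"], "EMR")

  # identity with the empty graph; commutative and idempotent on edge sets
  e0 <- build_graph(association_set(NULL), "empty")
  expect_setequal(pair_key(merge_graphs(g2, e0)$edges), pair_key(g2$edges))
  expect_setequal(pair_key(merge_graphs(g1, g2)$edges),
                  pair_key(merge_graphs(g2, g1)$edges))
  expect_setequal(pair_key(merge_graphs(m, m)$edges), pair_key(m$edges))
  g3 <- build_graph(association_set(
    data.frame(phenotype_id = "p3", disease_id = "d2")), "x")
  expect_setequal(pair_key(merge_graphs(merge_graphs(g1, g2), g3)$edges),
                  pair_key(merge_graphs(g1, merge_graphs(g2, g3))$edges))
})

test_that("restriction drops out-of-set diseases and isolated phenotypes", {
  pairs <- data.frame(
    phenotype_id = c("p1", "p2", "p2", "p3", "p4"),
    disease_id = c("d1", "d1", "d2", "d3", "d4")
  )
  g <- build_graph(association_set(pairs), "fix")
  r <- restrict_to_diseases(g, c("d1", "d2"))
  expect_setequal(r$U, c("d1", "d2"))
  expect_setequal(r$V, c("p1", "p2"))  # p3, p4 lose all edges
  expect_equal(nrow(r$edges), 3)
  expect_equal(length(restrict_to_diseases(g, character())$U), 0)
  full <- restrict_to_diseases(g, g$U)
  expect_setequal(pair_key(full$edges), pair_key(g$edges))
})

test_that("graph statistics follow the total-vertex-count conventions", {
  # complete bipartite K_{2,3}
  k23 <- build_graph(association_set(expand.grid(
    phenotype_id = c("p1", "p2", "p3"), disease_id = c("d1", "d2"),
    stringsAsFactors = FALSE)), "k23")
  s <- graph_stats(k23)
  expect_equal(s$n_edges, 6)
  expect_equal(s$density, 0.6)         # 2*6 / (5*4)
  expect_equal(s$average_degree, 2.4)  # 2*6 / 5

  e <- graph_stats(build_graph(association_set(NULL)))
  expect_equal(e$density, 0)
  expect_equal(e$average_degree, 0)

  # the density/average-degree identity and the handshake identity
  withr::with_seed(606, {
    ts <- random_transactions(30)
    rules <- enumerate_rules(ts)
    g <- build_graph(association_set(rules[c("phenotype_id", "disease_id")]))
    s <- graph_stats(g)
    n_total <- s$n_disease + s$n_phenotype
    expect_equal(s$average_degree, s$density * (n_total - 1), tolerance = 1e-9)
    expect_equal(sum(table(g$edges$disease_id)) + sum(table(g$edges$phenotype_id)),
                 2 * s$n_edges)
  })
})

test_that("degree ranking sorts by degree then identifier", {
  pairs <- data.frame(
    phenotype_id = c("p1", "p2", "p3", "p1", "p9"),
    disease_id = c("d1", "d1", "d1", "d2", "d3")
  )
  g <- build_graph(association_set(pairs), "fix")
  top <- top_degree_diseases(g, k = 2)
  expect_equal(top$disease_id, c("d1", "d2"))  # tie d2/d3 broken by id
  expect_equal(top$degree, c(3L, 1L))
  all_rank <- top_degree_diseases(g, k = 100)
  expect_equal(nrow(all_rank), 3)
  expect_equal(sum(all_rank$degree), nrow(g$edges))
  expect_true(all(diff(all_rank$degree) <= 0))
})

test_that("set overlap bookkeeping mirrors |B| - |shared|", {
  a <- association_set(data.frame(
    phenotype_id = c("p1", "p2", "p3"), disease_id = c("d1", "d1", "d2")))
  b <- association_set(data.frame(
    phenotype_id = c("p1", "p4"), disease_id = c("d1", "d3")), provenance = "EMR")
  ov <- association_set_overlap(a, b)
  assoc <- ov[ov$entity == "association", ]
  expect_equal(assoc$n_shared, 1)
  expect_equal(assoc$n_b_only, 1)
  dis <- ov[ov$entity == "disease", ]
  expect_equal(dis$n_b_only, dis$n_b - dis$n_shared)
})

test_that("GraphML and node-link JSON exports are readable and faithful", {
  g <- build_graph(three_pair_set(), "export")
  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), 4)
  expect_equal(igraph::gsize(ig), 3)
  expect_setequal(igraph::V(ig)$bipartite, c("disease", "phenotype"))

  js <- tempfile(fileext = ".json")
  write_graph_json(g, js)
  doc <- jsonlite::read_json(js)
  expect_length(doc$nodes, 4)
  expect_length(doc$links, 3)
  rar <- vapply(doc$nodes[vapply(doc$nodes, function(n) n$bipartite == "disease",
                                 logical(1))],
                function(n) n$rarity, character(1))
  expect_setequal(rar, c("RD", "CD"))
})
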