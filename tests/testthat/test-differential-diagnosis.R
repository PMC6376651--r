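test_that("Jaccard similarity is intersection over union", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(character(), "a"), 0)
  expect_error(jaccard(character(), character()), "undefined")
})

test_that("Jaccard is symmetric and 1 - J is a metric on random sets", {
  withr::with_seed(707, {
    pool <- letters
    sets <- replicate(12, sample(pool, sample(1:8, 1)), simplify = FALSE)
    for (i in 1:11) {
      expect_equal(jaccard(sets[[i]], sets[[i + 1]]),
                   jaccard(sets[[i + 1]], sets[[i]]))
    }
    combos <- utils::combn(12, 3)
    for (k in seq_len(ncol(combos))) {
      a <- sets[[combos[1, k]]]; b <- sets[[combos[2, k]]]; c_ <- sets[[combos[3, k]]]
      dab <- 1 - jaccard(a, b); dbc <- 1 - jaccard(b, c_); dac <- 1 - jaccard(a, c_)
      expect_lte(dac, dab + dbc + 1e-12)
    }
  })
})

test_that("profiles group significant phenotypes per disease", {
  sig <- data.frame(phenotype_id = c("p1", "p2", "p3"),
                    disease_id = c("d1", "d1", "d2"))
  prof <- build_profiles(sig)
  expect_equal(prof$d1, c("p1", "p2"))
  expect_equal(prof$d2, "p3")

  expect_length(build_profiles(data.frame(phenotype_id = character(),
                                          disease_id = character())), 0)

  # knowledge-base pass-through mode equals raw adjacency
  kb <- association_set(sig)
  expect_equal(unclass(build_profiles(kb, source_graph = "KB")),
               unclass(prof), ignore_attr = TRUE)

  # pairs outside the supplied graph are dropped with a warning
  g <- build_graph(association_set(sig[1:2, ]))
  expect_warning(prof2 <- build_profiles(sig, graph = g), "dropped")
  expect_null(prof2$d2)
})

test_that("similarity graph edges equal brute-force pairwise Jaccard", {
  profs <- structure(list(
    d1 = c("a", "b", "c"), d2 = c("b", "c", "d"),
    d3 = c("x", "y"), d4 = c("a", "b", "c")
  ), class = "phenotype_profiles", source_graph = "fix")
  g <- build_similarity_graph(profs, disease_labels = c(d3 = "common"))
  # d3 is disjoint from everything: no zero-weight edges
  expect_equal(nrow(g$edges), 3)
  for (i in seq_len(nrow(g$edges))) {
    expect_equal(g$edges$weight[i],
                 brute_jaccard(profs[[g$edges$disease_i[i]]],
                               profs[[g$edges$disease_j[i]]]))
  }
  expect_equal(g$edges$weight[g$edges$disease_i == "d1" &
                                g$edges$disease_j == "d4"], 1)
  expect_equal(g$nodes$rarity, c("RD", "RD", "CD", "RD"))

  # min_weight = 1 is exclusive: even identical profiles form no edge
  strict <- build_similarity_graph(profs, min_weight = 1)
  expect_equal(nrow(strict$edges), 0)
  nearly <- build_similarity_graph(profs, min_weight = 0.99)
  expect_equal(nrow(nearly$edges), 1)
})

test_that("candidate ranking is a descending, deterministic neighbour sort", {
  profs <- structure(list(
    q = c("a", "b", "c", "d"), d1 = c("a", "b", "c"), d2 = c("a", "b"),
    d3 = c("a", "b"), d4 = "z"
  ), class = "phenotype_profiles", source_graph = "fix")
  g <- build_similarity_graph(profs)
  r <- rank_candidates(g, "q", k = 10)
  expect_equal(r$disease_id, c("d1", "d2", "d3"))  # tie d2/d3 by id
  expect_equal(r$score, c(0.75, 0.5, 0.5))
  expect_equal(r$rank, 1:3)
  expect_equal(rank_candidates(g, "q", k = 1)$disease_id, "d1")
  expect_equal(nrow(rank_candidates(g, "d4", k = 5)), 0)
  expect_error(rank_candidates(g, "nope", k = 5), "nope")

  # brute-force sort oracle against all-pairs Jaccard with the query
  want <- sort(vapply(c("d1", "d2", "d3"),
                      function(d) brute_jaccard(profs$q, profs[[d]]), numeric(1)),
               decreasing = TRUE)
  expect_equal(r$score, unname(want))
})

test_that("merged-profile candidates cover each source's candidates", {
  kb_prof <- build_profiles(data.frame(phenotype_id = c("a", "b", "b"),
                                       disease_id = c("q", "q", "d1")))
  emr_prof <- build_profiles(data.frame(phenotype_id = c("a", "c", "c"),
                                        disease_id = c("q", "q", "d2")))
  merged <- merge_profiles(kb_prof, emr_prof)
  expect_equal(merged$q, c("a", "b", "c"))
  cands <- function(p) {
    g <- build_similarity_graph(p)
    if (!("q" %in% g$nodes$disease_id)) return(character())
    rank_candidates(g, "q", k = Inf)$disease_id
  }
  expect_true(all(cands(kb_prof) %in% cands(merged)))
  expect_true(all(cands(emr_prof) %in% cands(merged)))
})

test_that("similarity-graph JSON export round-trips with one center node", {
  profs <- structure(list(d1 = c("a", "b"), d2 = c("b", "c"), d3 = c("a", "b")),
                     class = "phenotype_profiles", source_graph = "fix")
  g <- build_similarity_graph(profs, disease_labels = c(d2 = "common"))
  path <- tempfile(fileext = ".json")
  export_similarity_graph(g, "d1", path)
  back <- read_similarity_graph(path)
  expect_equal(back$nodes[order(back$nodes$disease_id), ],
               g$nodes[order(g$nodes$disease_id), ], ignore_attr = TRUE)
  expect_equal(back$edges[order(back$edges$disease_i, back$edges$disease_j), ],
               g$edges[order(g$edges$disease_i, g$edges$disease_j), ],
               ignore_attr = TRUE)
  expect_equal(attr(back, "center"), "d1")
  doc <- jsonlite::read_json(path)
  expect_equal(sum(vapply(doc$nodes, function(n) isTRUE(n$center), logical(1))), 1)

  # golden fixture: stored file for the same 3-node graph
  golden <- test_path("golden_similarity_3node.json")
  expect_identical(readLines(path), readLines(golden))
})
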