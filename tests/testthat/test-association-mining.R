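# Hand-worked 4-patient cohort used across several blocks: phenotype p1 in
# patients 1 and 2, disease d1 in patients 2 and 3.
four_patients <- function() {
  transaction_set(
    phenotypes = list(a = "p1", b = "p1", c = character(), d = character()),
    diseases = list(a = character(), b = "d1", c = "d1", d = character())
  )
}

test_that("support counts unique patients holding the itemset", {
  ts <- four_patients()
  expect_equal(compute_support(ts, "p1"), 0.5)
  expect_equal(compute_support(ts, "d1"), 0.5)
  expect_equal(compute_support(ts, c("p1", "d1")), 0.25)
  expect_equal(compute_support(ts, "absent"), 0)
  all_ts <- transaction_set(phenotypes = list(a = "p", b = "p"),
                            diseases = list(a = "d", b = "d"))
  expect_equal(compute_support(all_ts, "p"), 1)
  expect_error(compute_support(transaction_set(stats::setNames(list(), character()),
                                               stats::setNames(list(), character())),
                               "p"), "empty")
})

test_that("confidence is support(PD)/support(P) with guarded domain", {
  expect_equal(compute_confidence(0.25, 0.5), 0.5)
  expect_equal(compute_confidence(0.5, 0.5), 1)
  expect_equal(compute_confidence(0, 0.5), 0)
  expect_error(compute_confidence(0.1, 0), "undefined")
  expect_error(compute_confidence(0.6, 0.5), "exceed")
})

test_that("rule enumeration matches the hand-counted example", {
  rules <- enumerate_rules(four_patients())
  expect_equal(nrow(rules), 1)
  expect_equal(rules$phenotype_id, "p1")
  expect_equal(rules$disease_id, "d1")
  expect_equal(rules$confidence, 0.5)

  none <- transaction_set(phenotypes = list(a = "p1", b = character()),
                          diseases = list(a = character(), b = "d1"))
  expect_equal(nrow(enumerate_rules(none)), 0)
})

test_that("rule enumeration equals brute force on random cohorts", {
  withr::with_seed(101, {
    for (trial in 1:20) {
      ts <- random_transactions(sample(5:50, 1))
      got <- enumerate_rules(ts)
      want <- brute_rules(ts)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        got <- got[order(got$phenotype_id, got$disease_id), ]
        want <- want[order(want$phenotype_id, want$disease_id), ]
        rownames(got) <- rownames(want) <- NULL
        expect_equal(as.data.frame(got), want)
      }
    }
  })
})

test_that("every enumerated rule satisfies the support/confidence identities", {
  withr::with_seed(202, {
    ts <- random_transactions(40)
    rules <- enumerate_rules(ts)
    expect_true(all(rules$support_pd > 0))
    expect_true(all(rules$support_pd <= pmin(rules$support_p, rules$support_d) + 1e-15))
    expect_equal(rules$confidence * rules$support_p, rules$support_pd,
                 tolerance = 1e-12)
  })
})

test_that("rare-only mode drops rules whose consequent is a common disease", {
  ts <- transaction_set(
    phenotypes = list(a = "p1", b = "p1"),
    diseases = list(a = "rare_d", b = "common_d")
  )
  labels <- c(rare_d = "rare", common_d = "common")
  all_rules <- enumerate_rules(ts)
  rare_rules <- enumerate_rules(ts, rare_only = TRUE, disease_labels = labels)
  expect_setequal(all_rules$disease_id, c("rare_d", "common_d"))
  expect_equal(rare_rules$disease_id, "rare_d")
  expect_error(enumerate_rules(ts, rare_only = TRUE), "disease_labels")
})

test_that("two-stage selection reproduces the hand filter", {
  rules <- structure(data.frame(
    phenotype_id = sprintf("p%d", 1:6), disease_id = sprintf("d%d", 1:6),
    support_p = rep(0.5, 6), support_d = rep(0.5, 6),
    support_pd = c(0.40, 0.30, 0.20, 0.10, 0.05, 0.01),
    confidence = c(0.80, 0.20, 0.90, 0.70, 0.95, 0.10)
  ), class = c("association_rules", "data.frame"))
  # mean support = 0.17666..., stage-1 survivors rows 1:3;
  # mean confidence of survivors = 0.6333..., stage-2 survivors rows 1 and 3
  out <- select_rules(rules, mining_thresholds("mean", "mean"))
  expect_setequal(out$phenotype_id, c("p1", "p3"))
  expect_equal(attr(out, "support_threshold"), mean(rules$support_pd))
  expect_equal(attr(out, "confidence_threshold"), mean(c(0.8, 0.2, 0.9)))

  # explicit 0/0 keeps everything (reordered by confidence desc)
  all_out <- select_rules(rules, mining_thresholds(0, 0))
  expect_setequal(all_out$phenotype_id, rules$phenotype_id)
  expect_equal(all_out$confidence, sort(rules$confidence, decreasing = TRUE))

  # a single rule always survives mean mode (x >= mean(x))
  single <- select_rules(rules[3, ], mining_thresholds("mean", "mean"))
  expect_equal(nrow(single), 1)

  # idempotence under the realised explicit thresholds
  again <- select_rules(out, mining_thresholds(attr(out, "support_threshold"),
                                               attr(out, "confidence_threshold")))
  expect_equal(as.data.frame(again), as.data.frame(out))

  expect_error(select_rules(rules[0, ], mining_thresholds("mean", "mean")),
               "empty")
})

test_that("characterization grid conserves rule counts and matches margins", {
  withr::with_seed(303, {
    ts <- random_transactions(40)
    rules <- enumerate_rules(ts)
    s_edges <- seq(0, max(rules$support_pd), length.out = 6)
    c_edges <- seq(0, 1, length.out = 5)
    grid <- characterize_rules(rules, s_edges, c_edges)
    expect_equal(sum(grid$counts), nrow(rules))
    # marginals match 1-D histograms (same binning convention)
    s_bin <- pmin(findInterval(rules$support_pd, s_edges, rightmost.closed = TRUE), 5)
    expect_equal(rowSums(grid$counts), as.vector(table(factor(s_bin, levels = 1:5))))
    # the count of rules above (s, c) never increases in either threshold
    cum <- function(s, c) sum(rules$support_pd >= s & rules$confidence >= c)
    for (s in s_edges) {
      vals <- vapply(c_edges, function(c) cum(s, c), numeric(1))
      expect_true(all(diff(vals) <= 0))
    }
  })

  one <- structure(data.frame(phenotype_id = "p", disease_id = "d",
                              support_p = 0.5, support_d = 0.5,
                              support_pd = 0.5, confidence = 1),
                   class = c("association_rules", "data.frame"))
  expect_equal(characterize_rules(one, c(0, 1), c(0, 1))$counts,
               matrix(1L, 1, 1))
  expect_error(characterize_rules(one, c(0, 0.4), c(0, 1)), "outside")
})
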