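test_that("degenerate cohort specs yield empty transactions", {
  spec <- cohort_spec(
    n_patients = 5,
    diseases = list(disease_spec("d1", TRUE, prevalence = 0,
                                 associated_phenotypes = data.frame(
                                   phenotype_id = "p1", emission_probability = 0.9))),
    n_background_phenotypes = 3, background_phenotype_rate = 0, seed = 1
  )
  ts <- generate_cohort(spec)
  expect_equal(ts$n_patients, 5)
  expect_true(all(lengths(ts$phenotypes) == 0))
  expect_true(all(lengths(ts$diseases) == 0))
})

test_that("cohort generation is deterministic for a fixed spec and seed", {
  spec <- demo_cohort_spec(seed = 42)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_transactions(generate_cohort(spec), f1)
  write_transactions(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empirical emission probability converges to the planted value", {
  spec <- cohort_spec(
    n_patients = 10000,
    diseases = list(disease_spec(
      "d1", TRUE, prevalence = 0.5,
      associated_phenotypes = data.frame(phenotype_id = "p1",
                                         emission_probability = 0.9),
      leak_probability = 0.05)),
    seed = 99
  )
  ts <- generate_cohort(spec)
  carrier <- vapply(ts$diseases, function(x) "d1" %in% x, logical(1))
  with_phen <- vapply(ts$phenotypes, function(x) "p1" %in% x, logical(1))
  # binomial SE at n ~ 5000 carriers is ~0.004, so +-0.02 is ~5 SE
  expect_equal(mean(with_phen[carrier]), 0.9, tolerance = 0.02 / 0.9)
  expect_lt(abs(mean(with_phen[!carrier]) - 0.05), 0.02)
})

test_that("invalid probabilities are rejected with the field named", {
  expect_error(disease_spec("d", TRUE, prevalence = 1.5,
                            associated_phenotypes = NULL), "prevalence")
  expect_error(
    disease_spec("d", TRUE, 0.5,
                 data.frame(phenotype_id = "p", emission_probability = 2)),
    "emission_probability")
  expect_error(
    cohort_spec(10, list(disease_spec("d", TRUE, 0.5, NULL)),
                background_phenotype_rate = -0.1, seed = 1),
    "background_phenotype_rate")
  expect_error(
    disease_spec("d", TRUE, 0.5,
                 data.frame(phenotype_id = "p", emission_probability = 0.1),
                 leak_probability = 0.2),
    "emission_probability")
})

test_that("knowledge-base generation honours shared and KB-only counts", {
  spec <- demo_cohort_spec(seed = 7)
  planted <- planted_pairs(spec)

  empty <- generate_knowledge_base(spec, overlap_spec(0, 0), seed = 1)
  expect_equal(nrow(empty), 0)

  kb <- generate_knowledge_base(spec, overlap_spec(n_kb_only = 10, n_shared = 5),
                                seed = 3)
  expect_equal(nrow(kb), 15)
  shared <- intersect(pair_key(as.data.frame(kb)), pair_key(planted))
  expect_length(shared, 5)

  expect_error(
    generate_knowledge_base(spec, overlap_spec(0, nrow(planted) + 1), seed = 1),
    "planted")
})

test_that("knowledge-base TSV writer/reader round-trips pair sets", {
  spec <- demo_cohort_spec(seed = 7)
  kb <- generate_knowledge_base(spec, overlap_spec(8, 4), seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_kb_table(kb, path)
  back <- read_kb_table(path)
  expect_setequal(pair_key(as.data.frame(back)), pair_key(as.data.frame(kb)))
})

test_that("literature set realises the requested explained fractions exactly", {
  spec <- demo_cohort_spec(seed = 11)
  planted <- planted_pairs(spec)
  kb <- generate_knowledge_base(spec, overlap_spec(n_kb_only = 30, n_shared = 0),
                                seed = 2)
  lit <- generate_literature_set(
    kb, association_set(planted, provenance = "EMR"),
    overlap_spec(30, 0, n_literature_total = 100,
                 fraction_literature_explained_by_kb = 0.04,
                 fraction_literature_explained_by_emr = 0.08),
    seed = 4
  )
  expect_equal(nrow(lit), 100)
  expect_equal(explanatory_power(kb, lit), 4)
  expect_equal(explanatory_power(association_set(planted), lit), 8)

  # empty sources explain nothing, whatever the literature size
  lit0 <- generate_literature_set(
    association_set(NULL), association_set(NULL),
    overlap_spec(0, 0, n_literature_total = 20), seed = 1)
  expect_equal(explanatory_power(association_set(NULL), lit0), 0)

  expect_error(
    generate_literature_set(
      kb, association_set(planted),
      overlap_spec(30, 0, 100,
                   fraction_literature_explained_by_kb = 0.9,
                   fraction_literature_explained_by_emr = 0.9),
      seed = 1),
    "exceed")
})

test_that("gold standard equals planted truth at zero noise", {
  spec <- demo_cohort_spec(seed = 13)
  gold_tab <- generate_gold_standard(spec, noise = 0, seed = 1)
  planted <- planted_pairs(spec)
  expect_setequal(paste(gold_tab$disease_id, gold_tab$phenotype_id),
                  paste(planted$disease_id, planted$phenotype_id))

  gs <- build_gold_standard(list(gold_tab))
  # identical planted sets give gold Jaccard 1; the hand case 2/4 gives 0.5
  twin <- data.frame(disease_id = rep(c("dx", "dy"), each = 3),
                     phenotype_id = c("a", "b", "c", "a", "b", "c"))
  gs2 <- build_gold_standard(list(twin))
  expect_equal(gs2$similarity$score, 1.0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_true(all(gs$similarity$score >= 0 & gs$similarity$score <= 1))
})

test_that("gold-standard noise swaps phenotypes at the requested rate", {
  spec <- demo_cohort_spec(seed = 17)
  gold_noisy <- generate_gold_standard(spec, noise = 1, seed = 2)
  planted <- planted_pairs(spec)
  # with noise 1 every disease has exactly one decoy phenotype
  decoys <- grepl("^decoy_", gold_noisy$phenotype_id)
  expect_equal(sum(decoys), length(unique(planted$disease_id)))
  expect_equal(nrow(gold_noisy), nrow(planted))
})
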