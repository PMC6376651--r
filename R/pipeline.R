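# End-to-end pipeline orchestration.
#
# Stages: simulate (optional) -> mine -> filter -> graphs -> diagnose ->
# evaluate. Every stage writes its machine outputs under the configured
# output directory and is recorded, with its record counts, in a JSON run
# manifest. Reruns with the same configuration and seed reproduce
# byte-identical machine outputs (the manifest's timestamps excepted).

#' Build a pipeline configuration
#'
#' Either `synthetic = TRUE` (inputs are generated from the packaged demo
#' cohort specification with the configured seed and overlap) or all four
#' input paths must be given.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed driving every stochastic step.
#' @param synthetic generate the four inputs instead of reading them.
#' @param transactions,kb,literature,gold input file paths (ignored when
#'   `synthetic = TRUE`).
#' @param support,confidence mining thresholds ([mining_thresholds()]);
#'   `"mean"` or explicit fractions.
#' @param ci_level odds-ratio confidence level.
#' @param min_weight similarity-graph edge threshold (strict).
#' @param gold_threshold gold-positive similarity threshold (strict).
#' @param top_k candidates reported per query (default 15).
#' @param rare_only restrict mined rules to rare-disease consequents.
#' @param query query disease for the differential-diagnosis stages; default
#'   is the first rare disease of the demo cohort.
#' @param overlap an [overlap_spec()] used when `synthetic = TRUE`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, synthetic = TRUE,
                            transactions = NULL, kb = NULL, literature = NULL,
                            gold = NULL, support = "mean", confidence = "mean",
                            ci_level = 0.95, min_weight = 0, gold_threshold = 0,
                            top_k = 15L, rare_only = FALSE,
                            query = "rare_disease_01",
                            overlap = demo_overlap_spec()) {
  check_count(seed, "seed")
  check_count(top_k, "top_k", min = 1)
  if (!synthetic && (is.null(transactions) || is.null(kb) ||
                     is.null(literature) || is.null(gold))) {
    stop("either synthetic = TRUE or all four input paths must be provided",
         call. = FALSE)
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), synthetic = isTRUE(synthetic),
         inputs = list(transactions = transactions, kb = kb,
                       literature = literature, gold = gold),
         thresholds = mining_thresholds(support, confidence),
         ci_level = ci_level, min_weight = min_weight,
         gold_threshold = gold_threshold, top_k = as.integer(top_k),
         rare_only = isTRUE(rare_only), query = normalize_id(query),
         overlap = overlap),
    class = "pipeline_config"
  )
}

#' Demo overlap specification
#'
#' Knowledge base of 72 pairs (12 drawn from the 60 planted cohort pairs, 60
#' knowledge-base-only); literature set of 200 pairs, 10% explained by the
#' knowledge base and 12% by the planted (minable) associations.
#'
#' @return an [overlap_spec()].
#' @export
demo_overlap_spec <- function() {
  overlap_spec(n_kb_only = 60, n_shared = 12, n_literature_total = 200,
               fraction_literature_explained_by_kb = 0.10,
               fraction_literature_explained_by_emr = 0.12)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `inputs:` is a
#' mapping of the four paths. The seed must be present in the file or
#' supplied as `seed`.
#'
#' @param path YAML file.
#' @param seed overrides / supplies the seed.
#' @param outdir overrides the output directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL, outdir = NULL) {
  y <- yaml::read_yaml(path)
  seed <- seed %||% y$seed
  if (is.null(seed)) stop("seed must be set in the config file or passed explicitly",
                          call. = FALSE)
  ov <- if (!is.null(y$overlap)) {
    do.call(overlap_spec, y$overlap)
  } else demo_overlap_spec()
  pipeline_config(
    outdir = outdir %||% y$outdir %||% ".",
    seed = seed,
    synthetic = y$synthetic %||% is.null(y$inputs),
    transactions = y$inputs$transactions, kb = y$inputs$kb,
    literature = y$inputs$literature, gold = y$inputs$gold,
    support = y$thresholds$support %||% "mean",
    confidence = y$thresholds$confidence %||% "mean",
    ci_level = y$ci_level %||% 0.95,
    min_weight = y$min_weight %||% 0,
    gold_threshold = y$gold_threshold %||% 0,
    top_k = y$top_k %||% 15L,
    rare_only = y$rare_only %||% FALSE,
    query = y$query %||% "rare_disease_01",
    overlap = ov
  )
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full enrichment and differential-diagnosis pipeline
#'
#' Executes simulate (when configured) -> mine -> filter -> graphs ->
#' diagnose -> evaluate, writing all stage outputs plus a JSON run manifest
#' (`manifest.json`) under `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with config snapshot, seed, package
#'   version, per-stage record counts and timestamps).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  stages <- list()
  t0 <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  record <- function(name, counts) {
    stages[[name]] <<- list(stage = name, counts = counts, finished = t0())
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------
  spec <- demo_cohort_spec(seed = config$seed)
  # rare/common labels are ground truth for synthetic runs; for real inputs
  # they default to "rare" at association-set construction (KB convention)
  labels <- if (config$synthetic) disease_labels_from_specs(spec) else character()
  if (config$synthetic) {
    run_stage("simulate", function() {
      ts <- generate_cohort(spec)
      kb <- generate_knowledge_base(spec, config$overlap, seed = config$seed + 1L)
      lit <- generate_literature_set(kb, planted_pairs(spec), config$overlap,
                                     seed = config$seed + 2L)
      gold <- generate_gold_standard(spec, noise = 0, seed = config$seed + 3L)
      write_transactions(ts, out("transactions.tsv"))
      write_kb_table(kb, out("kb.tsv"))
      write_pairs(lit, out("literature.tsv"))
      write_gold_table(gold, out("gold.tsv"))
      record("simulate", list(patients = ts$n_patients, kb_pairs = nrow(kb),
                              literature_pairs = nrow(lit), gold_rows = nrow(gold)))
      pipeline_log("simulate", "%d patients, %d KB pairs, %d literature pairs",
                   ts$n_patients, nrow(kb), nrow(lit))
    })
    paths <- list(transactions = out("transactions.tsv"), kb = out("kb.tsv"),
                  literature = out("literature.tsv"), gold = out("gold.tsv"))
  } else {
    paths <- config$inputs
  }

  # -- mine -------------------------------------------------------------
  ts <- kb <- lit <- gold_tab <- NULL
  selected <- significant <- NULL
  run_stage("mine", function() {
    ts <<- read_transactions(paths$transactions)
    kb <<- read_kb_table(paths$kb, disease_labels = labels)
    lit <<- read_pairs(paths$literature, provenance = "literature")
    gold_tab <<- read_gold_table(paths$gold)
    rules <- enumerate_rules(ts, rare_only = config$rare_only,
                             disease_labels = if (config$rare_only) labels)
    selected <<- select_rules(rules, config$thresholds)
    write_rules_tsv(rules, out("rules.tsv"))
    write_rules_tsv(selected, out("selected_rules.tsv"))
    if (nrow(rules) > 0) {
      grid <- characterize_rules(
        rules,
        support_bin_edges = seq(0, max(rules$support_pd), length.out = 11),
        confidence_bin_edges = seq(0, 1, length.out = 11)
      )
      write_grid_tsv(grid, out("rule_grid.tsv"))
    }
    record("mine", list(rules = nrow(rules), selected = nrow(selected)))
    pipeline_log("mine", "%d rules enumerated, %d selected", nrow(rules),
                 nrow(selected))
  })

  # -- filter -----------------------------------------------------------
  run_stage("filter", function() {
    instances <- association_instances(ts)
    significant <<- select_significant(selected, instances,
                                       ci_level = config$ci_level)
    write_rules_tsv(significant, out("significant.tsv"))
    record("filter", list(instances = nrow(instances),
                          significant = nrow(significant)))
    pipeline_log("filter", "%d significant of %d selected rules",
                 nrow(significant), nrow(selected))
  })

  # -- graphs -----------------------------------------------------------
  g_kb <- g_emr <- g_merged <- NULL
  run_stage("graphs", function() {
    emr_set <- association_set(significant[c("phenotype_id", "disease_id")],
                               disease_labels = labels, provenance = "EMR")
    g_kb <<- build_graph(kb, name = "KB")
    g_emr <<- build_graph(emr_set, name = "EMR")
    g_merged <<- merge_graphs(g_kb, g_emr, name = "merged")
    shared <- intersect(g_kb$U, g_emr$U)
    restricted <- lapply(list(KB = g_kb, EMR = g_emr, merged = g_merged),
                         restrict_to_diseases, keep = shared)
    write_tsv(graph_stats_table(restricted), out("graph_stats.tsv"))
    write_tsv(association_set_overlap(kb, emr_set), out("set_overlap.tsv"))
    for (nm in names(restricted)) {
      write_graphml(restricted[[nm]], out(sprintf("graph_%s.graphml", nm)))
      write_graph_json(restricted[[nm]], out(sprintf("graph_%s.json", nm)))
      write_tsv(top_degree_diseases(restricted[[nm]], k = config$top_k),
                out(sprintf("top_degree_%s.tsv", nm)))
    }
    record("graphs", list(shared_diseases = length(shared),
                          kb_edges = nrow(g_kb$edges),
                          emr_edges = nrow(g_emr$edges),
                          merged_edges = nrow(g_merged$edges)))
    pipeline_log("graphs", "KB %d / EMR %d / merged %d edges; %d shared diseases",
                 nrow(g_kb$edges), nrow(g_emr$edges), nrow(g_merged$edges),
                 length(shared))
  })

  # -- diagnose ---------------------------------------------------------
  sims <- NULL
  run_stage("diagnose", function() {
    prof_emr <- build_profiles(significant, source_graph = "EMR")
    prof_kb <- build_profiles(kb, source_graph = "KB")
    prof_merged <- merge_profiles(prof_kb, prof_emr, source_graph = "merged")
    profs <- list(KB = prof_kb, EMR = prof_emr, merged = prof_merged)
    sims <<- lapply(profs, build_similarity_graph,
                    min_weight = config$min_weight, disease_labels = labels)
    for (nm in names(sims)) {
      if (config$query %in% sims[[nm]]$nodes$disease_id) {
        ranking <- rank_candidates(sims[[nm]], config$query, k = config$top_k)
        write_ranking_tsv(ranking, out(sprintf("candidates_%s.tsv", nm)))
        export_similarity_graph(sims[[nm]], config$query,
                                out(sprintf("similarity_%s.json", nm)))
      }
    }
    record("diagnose", list(
      graphs = length(sims),
      edges = stats::setNames(lapply(sims, function(s) nrow(s$edges)), names(sims))
    ))
    pipeline_log("diagnose", "similarity edges: KB %d, EMR %d, merged %d",
                 nrow(sims$KB$edges), nrow(sims$EMR$edges),
                 nrow(sims$merged$edges))
  })

  # -- evaluate ---------------------------------------------------------
  run_stage("evaluate", function() {
    enriched <- association_set(
      rbind(as_pair_df(kb), significant[c("phenotype_id", "disease_id")]),
      disease_labels = labels, provenance = "both"
    )
    ep_i <- explanatory_power(kb, lit)
    ep_n <- explanatory_power(enriched, lit)
    report <- iep(nrow(lit), ep_i, ep_n)
    gold <- build_gold_standard(list(gold_tab))
    scores <- list()
    for (nm in names(sims)) {
      universe <- union(names(gold$profiles), sims[[nm]]$nodes$disease_id)
      predicted <- if (config$query %in% sims[[nm]]$nodes$disease_id) {
        rank_candidates(sims[[nm]], config$query, k = Inf)$disease_id
      } else character()
      sc <- score_candidates(predicted, gold, config$query, universe = universe,
                             gold_threshold = config$gold_threshold)
      scores[[nm]] <- c(sc$confusion, sc$metrics)
    }
    jsonlite::write_json(
      list(explanatory_power = unclass(report), diagnosis = scores),
      out("evaluation.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    record("evaluate", list(literature = nrow(lit), explained_initial = ep_i,
                            explained_enriched = ep_n))
    pipeline_log("evaluate", "EP %d -> %d of %d; IEP %.2f%%", ep_i, ep_n,
                 nrow(lit), report$iep_percent_2dp)
  })

  manifest <- list(
    package = "phenorich",
    version = as.character(utils::packageVersion("phenorich")),
    seed = config$seed,
    config = config_snapshot(config),
    stages = unname(stages),
    written = t0()
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(config) {
  list(
    outdir = config$outdir, seed = config$seed, synthetic = config$synthetic,
    inputs = config$inputs,
    thresholds = list(
      support = if (config$thresholds$support$mode == "mean") "mean"
                else config$thresholds$support$value,
      confidence = if (config$thresholds$confidence$mode == "mean") "mean"
                   else config$thresholds$confidence$value
    ),
    ci_level = config$ci_level, min_weight = config$min_weight,
    gold_threshold = config$gold_threshold, top_k = config$top_k,
    rare_only = config$rare_only, query = config$query,
    overlap = unclass(config$overlap)
  )
}
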