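# Enrichment and diagnostic-performance evaluation.
#
# Enrichment is quantified against an independent literature pair set:
# explanatory power EP = number of literature associations present in a
# knowledge base, and the increment of explanatory power
# IEP = 100 * (UK_i - UK_n) / UK_i, where UK_i and UK_n are the unexplained
# literature counts before and after enrichment. Diagnostic performance is
# scored against a curated gold standard via the confusion matrix over a
# candidate universe: sensitivity = TP / (TP + FN), specificity =
# TN / (TN + FP).

#' Explanatory power of a knowledge base
#'
#' Number of literature association pairs present in the knowledge base,
#' matched by exact equality of normalized identifiers.
#'
#' @param kb knowledge-base [association_set()] (or data frame of pairs).
#' @param literature literature [association_set()] (or data frame of pairs).
#' @return integer count.
#' @export
explanatory_power <- function(kb, literature) {
  kbp <- as_pair_df(kb)
  lit <- as_pair_df(literature)
  key <- function(df) paste(df$phenotype_id, df$disease_id, sep = "\r")
  sum(key(lit) %in% key(kbp))
}

#' Increment of explanatory power (IEP)
#'
#' With `UK_i = n_literature - explained_initial` unexplained associations
#' under the initial knowledge base and `UK_n = n_literature -
#' explained_enriched` under the enriched one, the increment of explanatory
#' power is `100 * (UK_i - UK_n) / UK_i` percent.
#'
#' @param n_literature size of the literature association set.
#' @param explained_initial literature pairs explained by the initial
#'   knowledge base.
#' @param explained_enriched literature pairs explained by the enriched
#'   knowledge base (>= `explained_initial`).
#' @return an `ep_report` list: `n_literature`, `explained_initial`,
#'   `explained_enriched`, `uk_initial`, `uk_enriched`, `iep_percent` (full
#'   precision) and `iep_percent_2dp` (half-up rounding for display).
#' @export
#' @examples
#' iep(124989, 4742, 10132)$iep_percent_2dp  # 4.48
iep <- function(n_literature, explained_initial, explained_enriched) {
  check_count(n_literature, "n_literature")
  check_count(explained_initial, "explained_initial")
  check_count(explained_enriched, "explained_enriched")
  if (explained_enriched < explained_initial) {
    stop("explained_enriched must be >= explained_initial (enrichment only adds pairs)",
         call. = FALSE)
  }
  if (explained_enriched > n_literature) {
    stop("explained counts cannot exceed the literature size", call. = FALSE)
  }
  uk_i <- n_literature - explained_initial
  uk_n <- n_literature - explained_enriched
  if (uk_i == 0) {
    stop("IEP is undefined: the initial knowledge base already explains the whole literature set",
         call. = FALSE)
  }
  pct <- 100 * (uk_i - uk_n) / uk_i
  structure(
    list(n_literature = n_literature, explained_initial = explained_initial,
         explained_enriched = explained_enriched,
         uk_initial = uk_i, uk_enriched = uk_n,
         iep_percent = pct, iep_percent_2dp = round_half_up(pct, 2)),
    class = "ep_report"
  )
}

#' @export
print.ep_report <- function(x, ...) {
  cat(sprintf("EP: %d -> %d of %d literature associations explained; IEP = %.2f%%\n",
              x$explained_initial, x$explained_enriched, x$n_literature,
              x$iep_percent_2dp))
  invisible(x)
}

#' Build a gold standard from curated disease-phenotype tables
#'
#' Per-disease profiles are the union across tables (e.g. a phenotype table
#' and a symptom table); the gold disease-disease similarity is the all-pairs
#' Jaccard similarity over diseases with nonempty profiles.
#'
#' @param gold_files list of data frames with columns `disease_id`,
#'   `phenotype_id`.
#' @return a `gold_standard`: list with `profiles` (named list disease ->
#'   phenotype set) and `similarity` (data frame `disease_i`, `disease_j`,
#'   `score`, `disease_i < disease_j`).
#' @export
build_gold_standard <- function(gold_files) {
  if (!length(gold_files)) stop("at least one gold table is required", call. = FALSE)
  if (is.data.frame(gold_files)) gold_files <- list(gold_files)
  long <- do.call(rbind, lapply(gold_files, function(df) {
    df <- as.data.frame(df)
    if (!all(c("disease_id", "phenotype_id") %in% names(df))) {
      stop("gold tables need columns disease_id and phenotype_id", call. = FALSE)
    }
    data.frame(disease_id = normalize_id(df$disease_id),
               phenotype_id = normalize_id(df$phenotype_id),
               stringsAsFactors = FALSE)
  }))
  profiles <- lapply(split(long$phenotype_id, long$disease_id),
                     function(x) sort(unique(x)))
  empty <- lengths(profiles) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d gold disease(s) with empty profiles", sum(empty)),
            call. = FALSE)
    profiles <- profiles[!empty]
  }
  profiles <- profiles[order(names(profiles))]
  ids <- names(profiles)
  similarity <- data.frame(disease_i = character(), disease_j = character(),
                           score = numeric(), stringsAsFactors = FALSE)
  if (length(ids) > 1) {
    combos <- utils::combn(ids, 2)
    similarity <- data.frame(
      disease_i = combos[1, ], disease_j = combos[2, ],
      score = vapply(seq_len(ncol(combos)), function(k) {
        jaccard(profiles[[combos[1, k]]], profiles[[combos[2, k]]])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(profiles = profiles, similarity = similarity),
            class = "gold_standard")
}

gold_similarity_to <- function(gold, query) {
  s <- gold$similarity
  inc <- s$disease_i == query | s$disease_j == query
  stats::setNames(s$score[inc],
                  ifelse(s$disease_i[inc] == query, s$disease_j[inc], s$disease_i[inc]))
}

#' Score a candidate ranking against the gold standard
#'
#' Gold positives are the universe diseases (query excluded) whose gold
#' similarity to the query strictly exceeds `gold_threshold`; predicted
#' positives are the candidate diseases. The confusion matrix partitions the
#' universe minus the query, and sensitivity/specificity follow.
#'
#' @param candidates a `candidate_ranking` ([rank_candidates()]) or character
#'   vector of predicted disease ids.
#' @param gold a `gold_standard` ([build_gold_standard()]).
#' @param query the query disease (must have a gold profile).
#' @param universe disease universe; defaults to the union of gold diseases
#'   and candidate diseases. Must contain the candidates and gold positives.
#' @param gold_threshold similarity cut defining gold positives (strict `>`,
#'   default 0).
#' @return a `diagnostic_score`: list with `confusion` (`tp`, `fp`, `fn`,
#'   `tn`) and `metrics` (`sensitivity`, `specificity`).
#' @export
score_candidates <- function(candidates, gold, query, universe = NULL,
                             gold_threshold = 0) {
  stopifnot(inherits(gold, "gold_standard"))
  check_probability(gold_threshold, "gold_threshold")
  query <- normalize_id(query)
  if (!(query %in% names(gold$profiles))) {
    stop(sprintf("query disease '%s' has no gold-standard profile", query),
         call. = FALSE)
  }
  predicted <- if (inherits(candidates, "candidate_ranking")) {
    candidates$disease_id
  } else normalize_id(candidates)
  predicted <- setdiff(unique(predicted), query)
  gold_sim <- gold_similarity_to(gold, query)
  positives <- names(gold_sim)[gold_sim > gold_threshold]
  if (is.null(universe)) {
    universe <- union(names(gold$profiles), predicted)
  } else {
    universe <- unique(normalize_id(universe))
  }
  universe <- setdiff(universe, query)
  if (!all(predicted %in% universe) || !all(positives %in% universe)) {
    stop("universe must contain all candidate diseases and gold positives",
         call. = FALSE)
  }
  tp <- length(intersect(predicted, positives))
  fp <- length(setdiff(predicted, positives))
  fn <- length(setdiff(positives, predicted))
  tn <- length(universe) - tp - fp - fn
  if (tp + fn == 0) {
    stop("sensitivity is undefined: no gold positives for this query", call. = FALSE)
  }
  if (tn + fp == 0) {
    stop("specificity is undefined: no gold negatives for this query", call. = FALSE)
  }
  structure(
    list(confusion = list(tp = tp, fp = fp, fn = fn, tn = tn),
         metrics = list(sensitivity = tp / (tp + fn),
                        specificity = tn / (tn + fp)),
         query = query, n_universe = length(universe),
         gold_threshold = gold_threshold),
    class = "diagnostic_score"
  )
}

#' @export
print.diagnostic_score <- function(x, ...) {
  cat(sprintf("query '%s': TP=%d FP=%d FN=%d TN=%d | sensitivity %.3f, specificity %.3f\n",
              x$query, x$confusion$tp, x$confusion$fp, x$confusion$fn,
              x$confusion$tn, x$metrics$sensitivity, x$metrics$specificity))
  invisible(x)
}
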