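# Association rule mining over patient transactions.
#
# Patients are transactions; their recorded phenotypes and diseases are
# items. Rules are one-item rules {Phenotype} -> {Disease}; support is the
# fraction of unique patients carrying an itemset and confidence is
# support(PD) / support(P). "Frequent itemsets" are the (P, D) pairs passing
# the support threshold -- with singleton antecedents no itemset lattice is
# needed.

#' Construct a transaction set
#'
#' @param phenotypes named list: patient id -> character vector of phenotype
#'   items.
#' @param diseases named list: patient id -> character vector of disease
#'   items. Names must match `phenotypes`.
#' @param note_multiplicity assumed number of notes per patient (metadata
#'   used only when instance counting explicitly requests it).
#' @return a `transaction_set`: list with `phenotypes`, `diseases` (named
#'   lists of deduplicated, normalized item sets) and `n_patients`.
#' @export
transaction_set <- function(phenotypes, diseases, note_multiplicity = 1L) {
  if (is.null(names(phenotypes)) || is.null(names(diseases)) ||
      !identical(names(phenotypes), names(diseases))) {
    stop("`phenotypes` and `diseases` must be named lists with identical patient ids",
         call. = FALSE)
  }
  if (anyDuplicated(names(phenotypes))) {
    stop("patient ids must be unique", call. = FALSE)
  }
  norm_sets <- function(l) lapply(l, function(x) sort(unique(normalize_id(x))))
  structure(
    list(phenotypes = norm_sets(phenotypes), diseases = norm_sets(diseases),
         n_patients = length(phenotypes),
         note_multiplicity = as.integer(note_multiplicity)),
    class = "transaction_set"
  )
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("<transaction_set> %d patients, %d distinct phenotypes, %d distinct diseases\n",
              x$n_patients, length(unique(unlist(x$phenotypes))),
              length(unique(unlist(x$diseases)))))
  invisible(x)
}

# Long data frame (patient_id, item_type, item_id), one row per patient-item.
transactions_long <- function(ts) {
  stopifnot(inherits(ts, "transaction_set"))
  pid <- names(ts$phenotypes)
  np <- lengths(ts$phenotypes)
  nd <- lengths(ts$diseases)
  data.frame(
    patient_id = c(rep(pid, np), rep(pid, nd)),
    item_type = rep(c("phenotype", "disease"), c(sum(np), sum(nd))),
    item_id = c(unlist(ts$phenotypes, use.names = FALSE),
                unlist(ts$diseases, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
}

#' Support of an itemset
#'
#' The fraction of unique patients whose combined phenotype + disease item
#' set contains every item in `items`.
#'
#' @param transactions a [transaction_set()].
#' @param items character vector of item identifiers (phenotypes and/or
#'   diseases).
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' ts <- transaction_set(
#'   phenotypes = list(a = "p1", b = "p1", c = character(), d = character()),
#'   diseases   = list(a = character(), b = "d1", c = "d1", d = character()))
#' compute_support(ts, "p1")          # 0.5
#' compute_support(ts, c("p1", "d1")) # 0.25
compute_support <- function(transactions, items) {
  stopifnot(inherits(transactions, "transaction_set"))
  if (transactions$n_patients == 0) {
    stop("transaction set is empty: support is undefined", call. = FALSE)
  }
  items <- unique(normalize_id(items))
  hit <- mapply(function(p, d) all(items %in% c(p, d)),
                transactions$phenotypes, transactions$diseases)
  sum(hit) / transactions$n_patients
}

#' Confidence of a rule {P} -> {D}
#'
#' @param support_PD joint support of the phenotype-disease itemset.
#' @param support_P support of the antecedent phenotype.
#' @return `support_PD / support_P`, a fraction in `[0, 1]`.
#' @export
compute_confidence <- function(support_PD, support_P) {
  if (any(support_P <= 0)) {
    stop("confidence is undefined when support(P) = 0", call. = FALSE)
  }
  if (any(support_PD > support_P + 1e-12)) {
    stop("support(PD) cannot exceed support(P)", call. = FALSE)
  }
  support_PD / support_P
}

#' Enumerate all one-item association rules
#'
#' Produces exactly one rule per (phenotype, disease) pair co-occurring in at
#' least one patient, with support and confidence computed over unique
#' patients.
#'
#' @param transactions a [transaction_set()].
#' @param rare_only if `TRUE`, restrict consequents to diseases labeled rare
#'   (knowledge-enrichment mode targets the rare-disease resource).
#' @param disease_labels named character vector (`"rare"`/`"common"` by
#'   normalized disease id); required when `rare_only = TRUE`.
#' @return data frame of class `association_rules` with columns
#'   `phenotype_id`, `disease_id`, `support_p`, `support_d`, `support_pd`,
#'   `confidence`, sorted by (`phenotype_id`, `disease_id`).
#' @export
enumerate_rules <- function(transactions, rare_only = FALSE, disease_labels = NULL) {
  stopifnot(inherits(transactions, "transaction_set"))
  n <- transactions$n_patients
  if (n == 0) stop("transaction set is empty", call. = FALSE)
  pid <- names(transactions$phenotypes)
  phen_long <- data.frame(
    patient_id = rep(pid, lengths(transactions$phenotypes)),
    phenotype_id = unlist(transactions$phenotypes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  dis_long <- data.frame(
    patient_id = rep(pid, lengths(transactions$diseases)),
    disease_id = unlist(transactions$diseases, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (rare_only) {
    if (is.null(disease_labels)) {
      stop("`disease_labels` is required when rare_only = TRUE", call. = FALSE)
    }
    keep <- names(disease_labels)[disease_labels == "rare"]
    dis_long <- dis_long[dis_long$disease_id %in% keep, , drop = FALSE]
  }
  co <- merge(phen_long, dis_long, by = "patient_id")
  if (nrow(co) == 0) {
    return(empty_rules())
  }
  pair_counts <- stats::aggregate(
    list(n_pd = co$patient_id),
    by = list(phenotype_id = co$phenotype_id, disease_id = co$disease_id),
    FUN = function(x) length(unique(x))
  )
  phen_counts <- table(phen_long$phenotype_id)   # item sets are deduplicated
  dis_counts <- table(dis_long$disease_id)
  rules <- data.frame(
    phenotype_id = pair_counts$phenotype_id,
    disease_id = pair_counts$disease_id,
    support_p = as.numeric(phen_counts[pair_counts$phenotype_id]) / n,
    support_d = as.numeric(dis_counts[pair_counts$disease_id]) / n,
    support_pd = pair_counts$n_pd / n,
    stringsAsFactors = FALSE
  )
  rules$confidence <- rules$support_pd / rules$support_p
  rules <- rules[order(rules$phenotype_id, rules$disease_id), , drop = FALSE]
  rownames(rules) <- NULL
  class(rules) <- c("association_rules", "data.frame")
  rules
}

empty_rules <- function() {
  structure(
    data.frame(phenotype_id = character(), disease_id = character(),
               support_p = numeric(), support_d = numeric(),
               support_pd = numeric(), confidence = numeric(),
               stringsAsFactors = FALSE),
    class = c("association_rules", "data.frame")
  )
}

#' Mining thresholds for rule selection
#'
#' Each threshold is either an explicit fraction or `"mean"`, in which case
#' the cut is the arithmetic mean of the corresponding metric over the rules
#' it is applied to (support over all input rules; confidence over the rules
#' surviving the support cut).
#'
#' @param support `"mean"` or an explicit minimum joint support in `[0, 1]`.
#' @param confidence `"mean"` or an explicit minimum confidence in `[0, 1]`.
#' @return a `mining_thresholds` object.
#' @export
mining_thresholds <- function(support = "mean", confidence = "mean") {
  parse_one <- function(x, field) {
    if (identical(x, "mean")) return(list(mode = "mean", value = NA_real_))
    check_probability(x, field)
    list(mode = "explicit", value = as.numeric(x))
  }
  structure(
    list(support = parse_one(support, "support"),
         confidence = parse_one(confidence, "confidence")),
    class = "mining_thresholds"
  )
}

#' Select top rules by a two-stage support then confidence filter
#'
#' Stage 1 keeps rules with `support_pd >=` the support threshold (the
#' frequent pairs); stage 2 keeps, among the survivors, rules with
#' `confidence >=` the confidence threshold. In mean mode the support
#' threshold is the mean joint support of all input rules and the confidence
#' threshold is the mean confidence of the stage-1 survivors. Comparisons use
#' `>=` since the thresholds are minima.
#'
#' @param rules an `association_rules` data frame from [enumerate_rules()].
#' @param thresholds a [mining_thresholds()].
#' @return the surviving rules sorted by (`confidence` desc, `support_pd`
#'   desc, `phenotype_id` asc, `disease_id` asc), with the applied thresholds
#'   in attributes `support_threshold` and `confidence_threshold`.
#' @export
select_rules <- function(rules, thresholds = mining_thresholds()) {
  stopifnot(inherits(thresholds, "mining_thresholds"))
  mean_mode <- thresholds$support$mode == "mean" ||
    thresholds$confidence$mode == "mean"
  if (nrow(rules) == 0 && mean_mode) {
    stop("mean-mode thresholds are undefined on an empty rule list", call. = FALSE)
  }
  s_cut <- if (thresholds$support$mode == "mean") mean(rules$support_pd)
           else thresholds$support$value
  frequent <- rules[rules$support_pd >= s_cut, , drop = FALSE]
  c_cut <- if (thresholds$confidence$mode == "mean") {
    if (nrow(frequent) == 0) Inf else mean(frequent$confidence)
  } else thresholds$confidence$value
  out <- frequent[frequent$confidence >= c_cut, , drop = FALSE]
  out <- out[order(-out$confidence, -out$support_pd, out$phenotype_id,
                   out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "support_threshold") <- s_cut
  attr(out, "confidence_threshold") <- if (is.infinite(c_cut)) NA_real_ else c_cut
  class(out) <- c("association_rules", "data.frame")
  out
}

#' Characterize rules on a support x confidence grid
#'
#' Counts rules per (support bin, confidence bin) cell for heatmap display.
#' Bins are left-closed, right-open; the last bin is closed on both sides.
#'
#' @param rules an `association_rules` data frame.
#' @param support_bin_edges strictly ascending bin edges covering all
#'   observed `support_pd` values.
#' @param confidence_bin_edges strictly ascending bin edges covering all
#'   observed `confidence` values.
#' @return a `characterization_grid`: list with `counts` (matrix, support
#'   bins x confidence bins) and the two edge vectors. `sum(counts)` equals
#'   the number of input rules.
#' @export
characterize_rules <- function(rules, support_bin_edges, confidence_bin_edges) {
  check_edges <- function(e, field) {
    if (length(e) < 2 || is.unsorted(e, strictly = TRUE)) {
      stop_field(field, "must be >= 2 strictly ascending values")
    }
  }
  check_edges(support_bin_edges, "support_bin_edges")
  check_edges(confidence_bin_edges, "confidence_bin_edges")
  bin_of <- function(x, edges, what) {
    if (any(x < edges[1] | x > edges[length(edges)])) {
      stop(sprintf("rule %s outside the binning range [%g, %g]",
                   what, edges[1], edges[length(edges)]), call. = FALSE)
    }
    i <- findInterval(x, edges, rightmost.closed = TRUE)
    pmin(i, length(edges) - 1)
  }
  si <- bin_of(rules$support_pd, support_bin_edges, "support")
  ci <- bin_of(rules$confidence, confidence_bin_edges, "confidence")
  counts <- matrix(0L, length(support_bin_edges) - 1, length(confidence_bin_edges) - 1)
  if (nrow(rules) > 0) {
    tab <- table(factor(si, levels = seq_len(nrow(counts))),
                 factor(ci, levels = seq_len(ncol(counts))))
    counts <- matrix(as.integer(tab), nrow(counts), ncol(counts))
  }
  structure(
    list(counts = counts, support_bin_edges = support_bin_edges,
         confidence_bin_edges = confidence_bin_edges),
    class = "characterization_grid"
  )
}
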