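# Odds-ratio significance filtering of mined associations.
#
# The odds ratio for a (disease D, phenotype P) pair is computed over
# association *instances*: deduplicated (patient, phenotype, disease) triples,
# so a patient carrying phenotype P together with diseases D1 and D2
# contributes the instances (P, D1) and (P, D2). A pair is retained when the
# lower bound of the odds-ratio confidence interval exceeds one.

#' Association instances of a transaction set
#'
#' @param transactions a [transaction_set()].
#' @param use_note_multiplicity if `TRUE`, replicate each patient's triples
#'   by the transaction set's `note_multiplicity`, emulating co-occurrence
#'   counting over multiple notes per patient. Defaults to `FALSE`
#'   (one instance per unique patient triple).
#' @return data frame of class `association_instances` with columns
#'   `patient_id`, `phenotype_id`, `disease_id` and attribute `n_instances`.
#' @export
association_instances <- function(transactions, use_note_multiplicity = FALSE) {
  stopifnot(inherits(transactions, "transaction_set"))
  pid <- names(transactions$phenotypes)
  rows <- mapply(function(p, d) length(p) * length(d),
                 transactions$phenotypes, transactions$diseases)
  keep <- pid[rows > 0]
  out <- do.call(rbind, lapply(keep, function(id) {
    expand.grid(phenotype_id = transactions$phenotypes[[id]],
                disease_id = transactions$diseases[[id]],
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(phenotype_id = character(), disease_id = character())
  }
  out <- data.frame(patient_id = rep(keep, rows[rows > 0][keep]),
                    out, stringsAsFactors = FALSE)
  if (use_note_multiplicity && transactions$note_multiplicity > 1) {
    out <- out[rep(seq_len(nrow(out)), each = transactions$note_multiplicity), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_instances") <- nrow(out)
  class(out) <- c("association_instances", "data.frame")
  out
}

#' Build the 2x2 contingency table for a disease-phenotype pair
#'
#' Partitions the instance universe into: `a` instances with both D and P,
#' `b` with D and a phenotype other than P, `c` with P and a disease other
#' than D, and `d` with neither.
#'
#' @param instances an [association_instances()] data frame.
#' @param disease_id,phenotype_id the pair (identifiers are normalized).
#' @return a `contingency_table`: list with counts `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(instances, disease_id, phenotype_id) {
  if (nrow(instances) == 0) stop("instance set is empty", call. = FALSE)
  D <- normalize_id(disease_id)
  P <- normalize_id(phenotype_id)
  is_d <- instances$disease_id == D
  is_p <- instances$phenotype_id == P
  structure(
    list(a = sum(is_d & is_p), b = sum(is_d & !is_p),
         c = sum(!is_d & is_p), d = sum(!is_d & !is_p)),
    class = "contingency_table"
  )
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = (a d) / (b c)`. When any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe correction) before both the estimate and the interval.
#' The interval is the Wald interval on the log odds ratio:
#' `exp(log(OR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))` on the (possibly
#' corrected) cells.
#'
#' @param table a `contingency_table` from [build_contingency()], or a list
#'   with elements `a`, `b`, `c`, `d`.
#' @param ci_level confidence level in (0, 1); default 0.95.
#' @return an `odds_ratio_result`: list with `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `ci_level`, `continuity_corrected`.
#' @export
#' @examples
#' odds_ratio(list(a = 10, b = 5, c = 2, d = 20))$odds_ratio  # 20
odds_ratio <- function(table, ci_level = 0.95) {
  check_probability(ci_level, "ci_level", allow_zero = FALSE, allow_one = FALSE)
  cells <- as.numeric(c(table$a, table$b, table$c, table$d))
  if (length(cells) != 4 || anyNA(cells) || any(cells < 0)) {
    stop("contingency table needs nonnegative cells a, b, c, d", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  se <- sqrt(sum(1 / cells))
  structure(
    list(odds_ratio = or,
         ci_lower = exp(log(or) - z * se),
         ci_upper = exp(log(or) + z * se),
         ci_level = ci_level,
         continuity_corrected = corrected),
    class = "odds_ratio_result"
  )
}

# Vectorized odds ratios for many pairs over one instance universe. Returns
# the same numbers as odds_ratio() on per-pair tables; kept internal so the
# scalar API stays the single documented definition.
odds_ratio_for_pairs <- function(instances, pairs, ci_level = 0.95) {
  n <- nrow(instances)
  key <- paste(instances$phenotype_id, instances$disease_id, sep = "\r")
  pair_tab <- table(key)
  n_d <- table(instances$disease_id)
  n_p <- table(instances$phenotype_id)
  pk <- paste(pairs$phenotype_id, pairs$disease_id, sep = "\r")
  a <- as.numeric(pair_tab[pk]); a[is.na(a)] <- 0
  b <- as.numeric(n_d[pairs$disease_id]) - a
  c_ <- as.numeric(n_p[pairs$phenotype_id]) - a
  d <- n - a - b - c_
  corrected <- a == 0 | b == 0 | c_ == 0 | d == 0
  a2 <- a + 0.5 * corrected; b2 <- b + 0.5 * corrected
  c2 <- c_ + 0.5 * corrected; d2 <- d + 0.5 * corrected
  or <- (a2 * d2) / (b2 * c2)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  data.frame(a = a, b = b, c = c_, d = d,
             odds_ratio = or,
             ci_lower = exp(log(or) - z * se),
             ci_upper = exp(log(or) + z * se),
             corrected = corrected)
}

#' Keep rules whose odds-ratio confidence-interval lower bound exceeds one
#'
#' For each rule's (phenotype, disease) pair, computes the odds ratio over
#' the instance universe and retains the rule when `ci_lower > 1` (strict).
#'
#' @param rules an `association_rules` data frame ([enumerate_rules()] or
#'   [select_rules()] output).
#' @param instances an [association_instances()] data frame covering every
#'   rule's pair.
#' @param ci_level confidence level for the odds-ratio interval.
#' @return data frame of class `significant_rules`: the surviving rules with
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `corrected` columns, sorted by
#'   (`odds_ratio` desc, `phenotype_id` asc, `disease_id` asc).
#' @export
select_significant <- function(rules, instances, ci_level = 0.95) {
  # re-filtering significant_rules output: recompute rather than duplicate
  rules <- as.data.frame(rules)
  rules <- rules[setdiff(names(rules),
                         c("odds_ratio", "ci_lower", "ci_upper", "corrected"))]
  if (nrow(rules) == 0) {
    out <- cbind(rules, data.frame(odds_ratio = numeric(), ci_lower = numeric(),
                                   ci_upper = numeric(), corrected = logical()))
    class(out) <- c("significant_rules", "data.frame")
    return(out)
  }
  or <- odds_ratio_for_pairs(instances, rules, ci_level = ci_level)
  if (any(or$a == 0)) {
    bad <- which(or$a == 0)[1]
    stop(sprintf("pair (%s, %s) does not occur in the instance set",
                 rules$phenotype_id[bad], rules$disease_id[bad]), call. = FALSE)
  }
  out <- cbind(as.data.frame(rules),
               or[c("odds_ratio", "ci_lower", "ci_upper", "corrected")])
  out <- out[out$ci_lower > 1, , drop = FALSE]
  out <- out[order(-out$odds_ratio, out$phenotype_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("significant_rules", "data.frame")
  out
}
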