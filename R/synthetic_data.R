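# Synthetic cohort and resource generator.
#
# The mining pipeline was designed for protected patient-level co-occurrence
# data that cannot be redistributed. This module generates all four pipeline
# inputs (patient transactions, knowledge-base associations, literature pair
# set, gold-standard disease profiles) with known ground truth: planted
# phenotype-disease association strengths, rare/common labels, and controlled
# overlap between the mined, knowledge-base, and literature association sets.

#' Specify one synthetic disease
#'
#' @param disease_id unique identifier.
#' @param is_rare logical; rare-disease flag carried through to candidate
#'   rankings as RD/CD labels.
#' @param prevalence probability in (0, 1] that a patient in the cohort
#'   carries the disease (prevalence within the studied cohort, not the
#'   population).
#' @param associated_phenotypes data frame with columns `phenotype_id` and
#'   `emission_probability`: the probability that the phenotype is recorded
#'   for a patient who has the disease.
#' @param leak_probability probability that an associated phenotype is
#'   recorded for a patient who does not have the disease (background
#'   comorbidity / coding noise). Must be strictly below every emission
#'   probability so planted associations are true associations.
#' @return a `disease_spec` object.
#' @export
disease_spec <- function(disease_id, is_rare, prevalence, associated_phenotypes,
                         leak_probability = 0) {
  if (length(disease_id) != 1 || !nzchar(disease_id)) {
    stop_field("disease_id", "must be a single non-empty string")
  }
  check_probability(prevalence, "prevalence", allow_zero = TRUE)
  check_probability(leak_probability, "leak_probability")
  ap <- as.data.frame(associated_phenotypes)
  if (nrow(ap) > 0) {
    if (!all(c("phenotype_id", "emission_probability") %in% names(ap))) {
      stop_field("associated_phenotypes",
                 "needs columns phenotype_id, emission_probability")
    }
    check_probability(ap$emission_probability, "emission_probability")
    if (anyDuplicated(ap$phenotype_id)) {
      stop_field("associated_phenotypes", "phenotype identifiers must be unique")
    }
    if (any(ap$emission_probability <= leak_probability & ap$emission_probability > 0)) {
      stop_field("emission_probability",
                 "must exceed leak_probability for planted associations")
    }
  }
  structure(
    list(disease_id = as.character(disease_id), is_rare = isTRUE(is_rare),
         prevalence = prevalence,
         associated_phenotypes = ap[, c("phenotype_id", "emission_probability"), drop = FALSE],
         leak_probability = leak_probability),
    class = "disease_spec"
  )
}

#' Specify a synthetic patient cohort
#'
#' @param n_patients number of patients (transactions) to simulate.
#' @param diseases list of [disease_spec()] objects.
#' @param n_background_phenotypes number of phenotypes unrelated to any
#'   disease, recorded independently per patient.
#' @param background_phenotype_rate per-patient probability of each
#'   background phenotype.
#' @param seed integer seed; the same spec and seed always reproduce the
#'   identical cohort.
#' @param note_multiplicity number of clinical notes each patient's items are
#'   assumed to appear in; affects only instance counting when explicitly
#'   requested downstream (default 1 = one note per patient).
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients, diseases, n_background_phenotypes = 0,
                        background_phenotype_rate = 0, seed,
                        note_multiplicity = 1L) {
  check_count(n_patients, "n_patients", min = 1)
  check_count(n_background_phenotypes, "n_background_phenotypes", min = 0)
  check_probability(background_phenotype_rate, "background_phenotype_rate")
  check_count(seed, "seed")
  check_count(note_multiplicity, "note_multiplicity", min = 1)
  if (!length(diseases) || !all(vapply(diseases, inherits, logical(1), "disease_spec"))) {
    stop_field("diseases", "must be a non-empty list of disease_spec objects")
  }
  ids <- vapply(diseases, `[[`, character(1), "disease_id")
  if (anyDuplicated(ids)) stop_field("diseases", "disease identifiers must be unique")
  structure(
    list(n_patients = as.integer(n_patients), diseases = diseases,
         n_background_phenotypes = as.integer(n_background_phenotypes),
         background_phenotype_rate = background_phenotype_rate,
         seed = as.integer(seed), note_multiplicity = as.integer(note_multiplicity)),
    class = "cohort_spec"
  )
}

#' Controlled overlap between knowledge-base, mined, and literature sets
#'
#' @param n_kb_only knowledge-base pairs absent from the planted cohort truth.
#' @param n_shared knowledge-base pairs that are also planted in the cohort.
#' @param n_literature_total size of the literature pair set.
#' @param fraction_literature_explained_by_kb fraction of literature pairs
#'   present in the knowledge base.
#' @param fraction_literature_explained_by_emr fraction of literature pairs
#'   present in the mined association set.
#' @return an `overlap_spec` object.
#' @export
overlap_spec <- function(n_kb_only, n_shared, n_literature_total = 0,
                         fraction_literature_explained_by_kb = 0,
                         fraction_literature_explained_by_emr = 0) {
  check_count(n_kb_only, "n_kb_only")
  check_count(n_shared, "n_shared")
  check_count(n_literature_total, "n_literature_total")
  check_probability(fraction_literature_explained_by_kb,
                    "fraction_literature_explained_by_kb")
  check_probability(fraction_literature_explained_by_emr,
                    "fraction_literature_explained_by_emr")
  structure(
    list(n_kb_only = as.integer(n_kb_only), n_shared = as.integer(n_shared),
         n_literature_total = as.integer(n_literature_total),
         fraction_literature_explained_by_kb = fraction_literature_explained_by_kb,
         fraction_literature_explained_by_emr = fraction_literature_explained_by_emr),
    class = "overlap_spec"
  )
}

#' Planted phenotype-disease pairs of a cohort specification
#'
#' @param diseases list of [disease_spec()] objects (or a `cohort_spec`).
#' @return data frame with columns `phenotype_id`, `disease_id`.
#' @export
planted_pairs <- function(diseases) {
  if (inherits(diseases, "cohort_spec")) diseases <- diseases$diseases
  out <- do.call(rbind, lapply(diseases, function(d) {
    if (nrow(d$associated_phenotypes) == 0) return(NULL)
    data.frame(phenotype_id = d$associated_phenotypes$phenotype_id,
               disease_id = d$disease_id, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(phenotype_id = character(), disease_id = character())
  }
  rownames(out) <- NULL
  out
}

#' Simulate a patient cohort as a transaction set
#'
#' Each patient is one transaction. A patient carries disease `D` with
#' probability `prevalence(D)`; given the disease, each associated phenotype
#' is recorded with its emission probability, and without it, with the
#' disease's leak probability. Background phenotypes are recorded
#' independently of disease status.
#'
#' @param spec a [cohort_spec()].
#' @return a [transaction_set()] with patients `pt00001`, `pt00002`, ...
#' @export
#' @examples
#' spec <- cohort_spec(
#'   n_patients = 50,
#'   diseases = list(disease_spec(
#'     "marfanoid_syndrome", is_rare = TRUE, prevalence = 0.3,
#'     associated_phenotypes = data.frame(
#'       phenotype_id = "arachnodactyly", emission_probability = 0.9),
#'     leak_probability = 0.02)),
#'   seed = 7)
#' generate_cohort(spec)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  n <- spec$n_patients
  with_seed(spec$seed, {
    disease_mat <- matrix(FALSE, n, length(spec$diseases),
                          dimnames = list(NULL, vapply(spec$diseases, `[[`,
                                                       character(1), "disease_id")))
    phen_ids <- unique(c(
      unlist(lapply(spec$diseases, function(d) d$associated_phenotypes$phenotype_id)),
      if (spec$n_background_phenotypes > 0)
        sprintf("background_phenotype_%02d", seq_len(spec$n_background_phenotypes))
    ))
    phen_mat <- matrix(FALSE, n, length(phen_ids), dimnames = list(NULL, phen_ids))
    for (j in seq_along(spec$diseases)) {
      d <- spec$diseases[[j]]
      carrier <- stats::runif(n) < d$prevalence
      disease_mat[, j] <- carrier
      for (k in seq_len(nrow(d$associated_phenotypes))) {
        p <- d$associated_phenotypes$phenotype_id[k]
        rate <- ifelse(carrier, d$associated_phenotypes$emission_probability[k],
                       d$leak_probability)
        phen_mat[, p] <- phen_mat[, p] | (stats::runif(n) < rate)
      }
    }
    if (spec$n_background_phenotypes > 0) {
      bg <- sprintf("background_phenotype_%02d", seq_len(spec$n_background_phenotypes))
      for (p in bg) {
        phen_mat[, p] <- phen_mat[, p] |
          (stats::runif(n) < spec$background_phenotype_rate)
      }
    }
    pid <- sprintf("pt%05d", seq_len(n))
    phen_list <- apply(phen_mat, 1, function(r) colnames(phen_mat)[r], simplify = FALSE)
    dis_list <- apply(disease_mat, 1, function(r) colnames(disease_mat)[r],
                      simplify = FALSE)
    if (ncol(phen_mat) == 0) phen_list <- rep(list(character()), n)
    if (ncol(disease_mat) == 0) dis_list <- rep(list(character()), n)
    names(phen_list) <- pid
    names(dis_list) <- pid
    transaction_set(phen_list, dis_list, note_multiplicity = spec$note_multiplicity)
  })
}

#' Rare/common labels implied by a list of disease specifications
#'
#' @param diseases list of [disease_spec()] objects.
#' @return named character vector, values `"rare"` or `"common"`.
#' @export
disease_labels_from_specs <- function(diseases) {
  if (inherits(diseases, "cohort_spec")) diseases <- diseases$diseases
  stats::setNames(
    ifelse(vapply(diseases, `[[`, logical(1), "is_rare"), "rare", "common"),
    normalize_id(vapply(diseases, `[[`, character(1), "disease_id"))
  )
}

#' Generate a synthetic knowledge-base association table
#'
#' Emulates a curated phenotype to rare-disease annotation resource:
#' `n_shared` of its pairs are drawn from the associations planted in the
#' cohort truth, and `n_kb_only` pairs involve knowledge-base-only phenotypes
#' (and, for every fourth pair, knowledge-base-only diseases) so they can
#' never be mined from the cohort.
#'
#' @param cohort_truth list of [disease_spec()] objects (or a `cohort_spec`).
#' @param overlap an [overlap_spec()].
#' @param seed integer seed.
#' @return an [association_set()] with provenance `"KB"`.
#' @export
generate_knowledge_base <- function(cohort_truth, overlap, seed) {
  if (inherits(cohort_truth, "cohort_spec")) cohort_truth <- cohort_truth$diseases
  check_count(seed, "seed")
  planted <- planted_pairs(cohort_truth)
  if (overlap$n_shared > nrow(planted)) {
    stop(sprintf("n_shared (%d) exceeds the %d planted pairs available",
                 overlap$n_shared, nrow(planted)), call. = FALSE)
  }
  labels <- disease_labels_from_specs(cohort_truth)
  with_seed(seed, {
    shared <- planted[sort(sample.int(nrow(planted), overlap$n_shared)), , drop = FALSE]
    kb_only <- NULL
    if (overlap$n_kb_only > 0) {
      n_new_dis <- ceiling(overlap$n_kb_only / 4)
      new_dis <- sprintf("kb_only_disease_%03d", seq_len(n_new_dis))
      dis_pool <- c(vapply(cohort_truth, `[[`, character(1), "disease_id"), new_dis)
      kb_only <- data.frame(
        phenotype_id = sprintf("kb_only_phenotype_%04d", seq_len(overlap$n_kb_only)),
        disease_id = sample(dis_pool, overlap$n_kb_only, replace = TRUE),
        stringsAsFactors = FALSE
      )
      labels <- c(labels, stats::setNames(rep("rare", n_new_dis), normalize_id(new_dis)))
    }
    association_set(rbind(shared, kb_only), disease_labels = labels,
                    provenance = "KB")
  })
}

#' Generate a synthetic literature association pair set
#'
#' Emulates a literature-derived predication set used to measure explanatory
#' power. Exact counts are constructed: `round(fraction * n_literature_total)`
#' pairs are sampled from the knowledge base only (excluding pairs also in the
#' mined set), the mined set only, and the remainder are novel pairs found in
#' neither source.
#'
#' @param kb knowledge-base [association_set()].
#' @param emr_pairs mined [association_set()] (or data frame of pairs).
#' @param overlap an [overlap_spec()] with literature fields set.
#' @param seed integer seed.
#' @return an [association_set()] with provenance `"literature"`.
#' @export
generate_literature_set <- function(kb, emr_pairs, overlap, seed) {
  check_count(seed, "seed")
  kb_pairs <- as_pair_df(kb)
  emr <- as_pair_df(emr_pairs)
  n_lit <- overlap$n_literature_total
  n_kb <- round(overlap$fraction_literature_explained_by_kb * n_lit)
  n_emr <- round(overlap$fraction_literature_explained_by_emr * n_lit)
  if (n_kb + n_emr > n_lit) {
    stop("requested explained fractions exceed the literature size", call. = FALSE)
  }
  key <- function(df) paste(df$phenotype_id, df$disease_id, sep = "\r")
  kb_pool <- kb_pairs[!(key(kb_pairs) %in% key(emr)), , drop = FALSE]
  emr_pool <- emr[!(key(emr) %in% key(kb_pairs)), , drop = FALSE]
  if (n_kb > nrow(kb_pool)) {
    stop(sprintf("need %d KB-only literature pairs but only %d KB pairs are outside the mined set",
                 n_kb, nrow(kb_pool)), call. = FALSE)
  }
  if (n_emr > nrow(emr_pool)) {
    stop(sprintf("need %d EMR-only literature pairs but only %d mined pairs are outside the KB",
                 n_emr, nrow(emr_pool)), call. = FALSE)
  }
  with_seed(seed, {
    pick_kb <- kb_pool[sort(sample.int(nrow(kb_pool), n_kb)), , drop = FALSE]
    pick_emr <- emr_pool[sort(sample.int(nrow(emr_pool), n_emr)), , drop = FALSE]
    n_novel <- n_lit - n_kb - n_emr
    novel <- if (n_novel > 0) {
      data.frame(phenotype_id = sprintf("literature_phenotype_%05d", seq_len(n_novel)),
                 disease_id = sprintf("literature_disease_%05d", seq_len(n_novel)),
                 stringsAsFactors = FALSE)
    }
    pairs <- rbind(pick_kb[c("phenotype_id", "disease_id")],
                   pick_emr[c("phenotype_id", "disease_id")], novel)
    labels <- c(attr(kb, "disease_labels"), attr(emr_pairs, "disease_labels"))
    association_set(pairs, disease_labels = labels, provenance = "literature",
                    default_label = "common")
  })
}

#' Generate a synthetic gold-standard disease-phenotype table
#'
#' Emulates a manually curated disease annotation resource: with `noise = 0`
#' each disease's gold phenotype set equals its planted associated
#' phenotypes. With probability `noise`, one randomly chosen phenotype of a
#' disease is swapped for a decoy phenotype absent from the planted truth,
#' exercising evaluation against an imperfect gold standard.
#'
#' @param diseases list of [disease_spec()] objects (or a `cohort_spec`).
#' @param noise per-disease swap probability in `[0, 1]`.
#' @param seed integer seed.
#' @return data frame with columns `disease_id`, `phenotype_id`.
#' @export
generate_gold_standard <- function(diseases, noise = 0, seed = 1L) {
  if (inherits(diseases, "cohort_spec")) diseases <- diseases$diseases
  check_probability(noise, "noise")
  check_count(seed, "seed")
  with_seed(seed, {
    rows <- lapply(diseases, function(d) {
      phens <- d$associated_phenotypes$phenotype_id
      if (length(phens) > 0 && stats::runif(1) < noise) {
        swap <- sample.int(length(phens), 1)
        phens[swap] <- sprintf("decoy_phenotype_%s_%02d", d$disease_id, swap)
      }
      if (length(phens) == 0) return(NULL)
      data.frame(disease_id = d$disease_id, phenotype_id = phens,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(disease_id = character(), phenotype_id = character())
    }
    rownames(out) <- NULL
    out
  })
}

#' Packaged demonstration cohort specification
#'
#' A cohort small enough for routine testing but large enough for odds-ratio
#' filtering to behave: 2,000 patients; 20 diseases (12 rare at within-cohort
#' prevalence 0.05, 8 common at 0.15); a pool of 40 associated phenotypes of
#' which disease `i` emits phenotypes `2i-1`, `2i` and `2i+1` (modulo 40) at
#' probability 0.8 with leak probability 0.02 in non-carriers, so consecutive
#' diseases share one phenotype and the similarity graph has planted
#' structure; plus 20 background phenotypes recorded independently at rate
#' 0.05.
#'
#' @param seed integer seed (default 20190214).
#' @return a [cohort_spec()].
#' @export
demo_cohort_spec <- function(seed = 20190214L) {
  n_dis <- 20L
  n_rare <- 12L
  diseases <- lapply(seq_len(n_dis), function(i) {
    rare <- i <= n_rare
    idx <- ((c(2L * i - 2L, 2L * i - 1L, 2L * i)) %% (2L * n_dis)) + 1L
    disease_spec(
      disease_id = sprintf("%s_disease_%02d", if (rare) "rare" else "common", i),
      is_rare = rare,
      prevalence = if (rare) 0.05 else 0.15,
      associated_phenotypes = data.frame(
        phenotype_id = sprintf("phenotype_%02d", sort(idx)),
        emission_probability = 0.8
      ),
      leak_probability = 0.02
    )
  })
  cohort_spec(
    n_patients = 2000L, diseases = diseases,
    n_background_phenotypes = 20L, background_phenotype_rate = 0.05,
    seed = seed
  )
}
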