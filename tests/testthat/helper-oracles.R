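# Brute-force oracles and random fixtures. These deliberately use the
# simplest possible implementations (explicit loops over patients and item
# pairs) so they stay independent of the package's vectorized code paths.

pair_key <- function(df) paste(df$phenotype_id, df$disease_id, sep = "|")

# Random small cohort: every patient gets each phenotype/disease
# independently with the given rates.
random_transactions <- function(n_patients, n_phen = 6, n_dis = 4,
                                phen_rate = 0.3, dis_rate = 0.3) {
  phens <- sprintf("p%02d", seq_len(n_phen))
  diss <- sprintf("d%02d", seq_len(n_dis))
  pid <- sprintf("pt%03d", seq_len(n_patients))
  phen_list <- lapply(pid, function(i) phens[stats::runif(n_phen) < phen_rate])
  dis_list <- lapply(pid, function(i) diss[stats::runif(n_dis) < dis_rate])
  transaction_set(stats::setNames(phen_list, pid), stats::setNames(dis_list, pid))
}

brute_support <- function(ts, items) {
  hits <- 0
  for (id in names(ts$phenotypes)) {
    pool <- c(ts$phenotypes[[id]], ts$diseases[[id]])
    if (all(items %in% pool)) hits <- hits + 1
  }
  hits / ts$n_patients
}

# O(patients x phenotypes x diseases) rule enumeration.
brute_rules <- function(ts) {
  phens <- sort(unique(unlist(ts$phenotypes)))
  diss <- sort(unique(unlist(ts$diseases)))
  rows <- list()
  for (p in phens) {
    for (d in diss) {
      n_pd <- n_p <- n_d <- 0
      for (id in names(ts$phenotypes)) {
        has_p <- p %in% ts$phenotypes[[id]]
        has_d <- d %in% ts$diseases[[id]]
        n_p <- n_p + has_p
        n_d <- n_d + has_d
        n_pd <- n_pd + (has_p && has_d)
      }
      if (n_pd > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          phenotype_id = p, disease_id = d,
          support_p = n_p / ts$n_patients, support_d = n_d / ts$n_patients,
          support_pd = n_pd / ts$n_patients,
          confidence = (n_pd / ts$n_patients) / (n_p / ts$n_patients),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

brute_contingency <- function(instances, D, P) {
  a <- b <- c_ <- d <- 0
  for (i in seq_len(nrow(instances))) {
    is_d <- instances$disease_id[i] == D
    is_p <- instances$phenotype_id[i] == P
    if (is_d && is_p) a <- a + 1
    else if (is_d) b <- b + 1
    else if (is_p) c_ <- c_ + 1
    else d <- d + 1
  }
  list(a = a, b = b, c = c_, d = d)
}

brute_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  length(u[u %in% a & u %in% b]) / length(u)
}

# Fraction of null (independent) phenotype-disease pairs flagged significant
# at the given CI level, for one simulated null cohort.
null_flag_fraction <- function(seed, n_patients = 400, ci_level = 0.95) {
  diseases <- lapply(1:3, function(i) {
    disease_spec(sprintf("null_disease_%d", i), is_rare = TRUE, prevalence = 0.1,
                 associated_phenotypes = data.frame(phenotype_id = character(),
                                                    emission_probability = numeric()))
  })
  spec <- cohort_spec(n_patients, diseases, n_background_phenotypes = 6,
                      background_phenotype_rate = 0.1, seed = seed)
  ts <- generate_cohort(spec)
  rules <- enumerate_rules(ts)
  if (nrow(rules) == 0) return(c(flagged = 0, tested = 0))
  sig <- select_significant(rules, association_instances(ts), ci_level = ci_level)
  c(flagged = nrow(sig), tested = nrow(rules))
}
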