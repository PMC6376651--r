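# Readers and writers for the pipeline's plain-text dialects.
#
# All dialects are tab-separated with '.' decimal separators; floats are
# written at full precision (with rounded display columns alongside where a
# report convention exists). Every writer/reader pair round-trips losslessly.

read_tsv_checked <- function(path, expected, header = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = header, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE)
  if (header && nrow(df) >= 0 && !all(expected %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(expected, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a transaction set
#'
#' Long-format TSV (`patient_id`, `item_type`, `item_id`, one row per
#' patient-item) or JSONL (one patient object per line with keys
#' `patient_id`, `phenotypes`, `diseases`).
#'
#' @param transactions a [transaction_set()].
#' @param path output path; format chosen by `format` or by a `.jsonl`
#'   extension.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(transactions, path,
                               format = if (grepl("\\.jsonl$", path)) "jsonl" else "tsv") {
  stopifnot(inherits(transactions, "transaction_set"))
  format <- match.arg(format, c("tsv", "jsonl"))
  if (format == "tsv") {
    write_tsv(transactions_long(transactions), path)
  } else {
    pid <- names(transactions$phenotypes)
    lines <- vapply(pid, function(id) {
      as.character(jsonlite::toJSON(
        list(patient_id = jsonlite::unbox(id),
             phenotypes = transactions$phenotypes[[id]],
             diseases = transactions$diseases[[id]])))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a transaction set
#'
#' @param path TSV (header `patient_id`, `item_type`, `item_id`) or JSONL
#'   file as written by [write_transactions()].
#' @param format `"tsv"` or `"jsonl"` (inferred from the extension by
#'   default).
#' @return a [transaction_set()].
#' @export
read_transactions <- function(path,
                              format = if (grepl("\\.jsonl$", path)) "jsonl" else "tsv") {
  format <- match.arg(format, c("tsv", "jsonl"))
  if (format == "tsv") {
    df <- read_tsv_checked(path, c("patient_id", "item_type", "item_id"))
    if (nrow(df) == 0) {
      stop(sprintf("%s: no transactions (support would be undefined)", path),
           call. = FALSE)
    }
    bad <- which(!(df$item_type %in% c("phenotype", "disease")))
    if (length(bad) > 0) {
      stop(sprintf("%s: unknown item_type '%s' on data line %d", path,
                   df$item_type[bad[1]], bad[1]), call. = FALSE)
    }
    pid <- unique(df$patient_id)
    phen <- split(df$item_id[df$item_type == "phenotype"],
                  factor(df$patient_id[df$item_type == "phenotype"], levels = pid))
    dis <- split(df$item_id[df$item_type == "disease"],
                 factor(df$patient_id[df$item_type == "disease"], levels = pid))
    transaction_set(phen, dis)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      stop(sprintf("%s: no transactions (support would be undefined)", path),
           call. = FALSE)
    }
    recs <- lapply(lines, jsonlite::fromJSON)
    pid <- vapply(recs, function(r) as.character(r$patient_id), character(1))
    phen <- stats::setNames(lapply(recs, function(r) as.character(unlist(r$phenotypes))), pid)
    dis <- stats::setNames(lapply(recs, function(r) as.character(unlist(r$diseases))), pid)
    transaction_set(phen, dis)
  }
}

#' Write a knowledge-base association table
#'
#' Four-column TSV: `disease_id`, `disease_name`, `phenotype_id`,
#' `phenotype_name`. Names default to the identifiers when the association
#' set carries none.
#'
#' @param assoc an [association_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kb_table <- function(assoc, path) {
  df <- as.data.frame(assoc)
  write_tsv(data.frame(disease_id = df$disease_id,
                       disease_name = df$disease_id,
                       phenotype_id = df$phenotype_id,
                       phenotype_name = df$phenotype_id,
                       stringsAsFactors = FALSE), path)
}

#' Read a knowledge-base association table
#'
#' Native dialect: header `disease_id`, `disease_name`, `phenotype_id`,
#' `phenotype_name`; lines starting with `#` are comments. Compatibility
#' dialect (`format = "annotation_tab"`): a headerless, tab-separated
#' phenotype-annotation layout whose first five columns are DB,
#' DB_Object_ID, DB_Name, Qualifier, HPO_ID; the disease id is
#' `DB:DB_Object_ID` and the phenotype id is the HPO term id. Duplicate
#' pairs are collapsed (a message reports how many).
#'
#' @param path input file.
#' @param format `"native"` or `"annotation_tab"`.
#' @param disease_labels optional named rare/common labels to attach.
#' @return an [association_set()] with provenance `"KB"`.
#' @export
read_kb_table <- function(path, format = c("native", "annotation_tab"),
                          disease_labels = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "native") {
    lines <- readLines(path)
    keep <- which(!startsWith(lines, "#") & nzchar(lines))
    if (length(keep) == 0) {
      warning(sprintf("%s: empty knowledge-base file", path), call. = FALSE)
      return(association_set(NULL, provenance = "KB"))
    }
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    header <- fields[[1]]
    if (!all(c("disease_id", "phenotype_id") %in% header)) {
      stop(sprintf("%s: expected header with disease_id and phenotype_id", path),
           call. = FALSE)
    }
    if (length(fields) == 1) {
      warning(sprintf("%s: empty knowledge-base file", path), call. = FALSE)
      return(association_set(NULL, provenance = "KB"))
    }
    body <- fields[-1]
    nf <- lengths(body)
    if (any(nf != length(header))) {
      bad <- which(nf != length(header))[1]
      stop(sprintf("%s: malformed row at line %d (%d of %d fields)", path,
                   keep[bad + 1], nf[bad], length(header)), call. = FALSE)
    }
    pairs <- data.frame(
      phenotype_id = vapply(body, `[[`, character(1), match("phenotype_id", header)),
      disease_id = vapply(body, `[[`, character(1), match("disease_id", header)),
      stringsAsFactors = FALSE
    )
  } else {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- vapply(fields, length, integer(1))
    if (length(fields) == 0) {
      warning(sprintf("%s: empty knowledge-base file", path), call. = FALSE)
      return(association_set(NULL, provenance = "KB"))
    }
    if (any(nf < 5)) {
      stop(sprintf("%s: malformed row at line %d (%d of >=5 fields)", path,
                   which(keep)[which(nf < 5)[1]], min(nf)), call. = FALSE)
    }
    pairs <- data.frame(
      phenotype_id = vapply(fields, `[[`, character(1), 5),
      disease_id = paste0(vapply(fields, `[[`, character(1), 1), ":",
                          vapply(fields, `[[`, character(1), 2)),
      stringsAsFactors = FALSE
    )
  }
  association_set(pairs, disease_labels = disease_labels, provenance = "KB")
}

#' Write/read a plain association pair table
#'
#' Two/three-column TSV: `phenotype_id`, `disease_id` and, when present,
#' `provenance`.
#'
#' @param pairs an [association_set()] or data frame of pairs.
#' @param path file path.
#' @return `path` (writer) / an [association_set()] (reader).
#' @export
write_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs)
  cols <- intersect(c("phenotype_id", "disease_id", "provenance"), names(df))
  write_tsv(df[cols], path)
}

#' @rdname write_pairs
#' @param provenance provenance applied when the file has no column.
#' @param disease_labels optional rare/common labels.
#' @export
read_pairs <- function(path, provenance = "EMR", disease_labels = character()) {
  df <- read_tsv_checked(path, c("phenotype_id", "disease_id"))
  association_set(df, disease_labels = disease_labels, provenance = provenance,
                  default_label = "common")
}

#' Write/read a gold-standard disease-phenotype table
#'
#' Two-column TSV: `disease_id`, `phenotype_id`.
#'
#' @param gold data frame with `disease_id`, `phenotype_id`.
#' @param path file path.
#' @return `path` (writer) / data frame (reader).
#' @export
write_gold_table <- function(gold, path) {
  write_tsv(as.data.frame(gold)[c("disease_id", "phenotype_id")], path)
}

#' @rdname write_gold_table
#' @export
read_gold_table <- function(path) {
  read_tsv_checked(path, c("disease_id", "phenotype_id"))
}

#' Write/read association rules
#'
#' TSV with columns `phenotype_id`, `disease_id`, `support_p`, `support_d`,
#' `support_pd`, `confidence` (full-precision floats), plus any odds-ratio
#' columns present (`odds_ratio`, `ci_lower`, `ci_upper`, `corrected`).
#'
#' @param rules an `association_rules` or `significant_rules` data frame.
#' @param path file path.
#' @return `path` (writer) / data frame with the same class (reader).
#' @export
write_rules_tsv <- function(rules, path) {
  df <- as.data.frame(rules)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write_tsv(df, path)
}

#' @rdname write_rules_tsv
#' @export
read_rules_tsv <- function(path) {
  df <- read_tsv_checked(path, c("phenotype_id", "disease_id", "support_pd"))
  cls <- if ("odds_ratio" %in% names(df)) "significant_rules" else "association_rules"
  class(df) <- c(cls, "data.frame")
  df
}

#' Write a characterization grid
#'
#' The count matrix as a TSV (support bins as rows) plus a `.edges.tsv`
#' sidecar holding the two bin-edge vectors for heatmap axes.
#'
#' @param grid a `characterization_grid` ([characterize_rules()]).
#' @param path path of the matrix TSV; the sidecar gets suffix `.edges.tsv`.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  m <- grid$counts
  dimnames(m) <- list(
    sprintf("support_bin_%02d", seq_len(nrow(m))),
    sprintf("confidence_bin_%02d", seq_len(ncol(m)))
  )
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  edges <- data.frame(
    axis = rep(c("support", "confidence"),
               c(length(grid$support_bin_edges), length(grid$confidence_bin_edges))),
    edge = c(grid$support_bin_edges, grid$confidence_bin_edges)
  )
  write_tsv(edges, paste0(path, ".edges.tsv"))
  invisible(path)
}

#' Write a candidate ranking
#'
#' TSV mirroring the standard top-k candidate table: `rank`, `disease_id`,
#' `rarity`, `jaccard` (4-decimal display) and `jaccard_full`
#' (full precision).
#'
#' @param ranking a `candidate_ranking` ([rank_candidates()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  df <- as.data.frame(ranking)
  out <- data.frame(rank = df$rank, disease_id = df$disease_id,
                    rarity = df$rarity,
                    jaccard = sprintf("%.4f", round_half_up(df$score, 4)),
                    jaccard_full = sprintf("%.17g", df$score),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
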