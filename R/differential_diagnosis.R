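# Differential diagnosis by Jaccard similarity of phenotype profiles.
#
# Each disease's profile is its set of significant phenotypes (odds-ratio
# filtered for mined associations; raw adjacency for knowledge-base graphs,
# where no patient counts exist). Diseases become nodes of a weighted graph
# whose edge weights are Jaccard similarities between profiles; candidates
# for a query disease are its neighbours ranked by descending weight.

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`.
#'
#' @param set_i,set_j character vectors (treated as sets).
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
jaccard <- function(set_i, set_j) {
  a <- unique(set_i); b <- unique(set_j)
  if (length(a) == 0 && length(b) == 0) {
    stop("Jaccard similarity is undefined for two empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Build per-disease significant-phenotype profiles
#'
#' `profile(D)` is the set of phenotypes P with a significant (P, D) pair;
#' when a graph is supplied the pair must also be one of its edges. Diseases
#' ending up with an empty profile are omitted with a warning.
#'
#' @param significant_pairs a `significant_rules` data frame
#'   ([select_significant()]) or any data frame of `phenotype_id`,
#'   `disease_id` pairs (e.g. a knowledge-base [association_set()], whose raw
#'   adjacency is used unfiltered).
#' @param graph optional `bipartite_graph` restricting pairs to its edges.
#' @param source_graph label recorded on the result.
#' @return a `phenotype_profiles` object: named list disease id -> character
#'   vector of phenotype ids, with attribute `source_graph`.
#' @export
build_profiles <- function(significant_pairs, graph = NULL, source_graph = "EMR") {
  pairs <- as_pair_df(significant_pairs)
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "bipartite_graph"))
    key <- function(df) paste(df$phenotype_id, df$disease_id, sep = "\r")
    dropped <- !(key(pairs) %in% key(graph$edges))
    if (any(dropped)) {
      warning(sprintf("%d significant pair(s) absent from graph '%s' were dropped",
                      sum(dropped), graph$name), call. = FALSE)
    }
    pairs <- pairs[!dropped, , drop = FALSE]
  }
  profiles <- split(pairs$phenotype_id, pairs$disease_id)
  profiles <- lapply(profiles, function(x) sort(unique(x)))
  empty <- lengths(profiles) == 0
  if (any(empty)) {
    warning(sprintf("omitting %d disease(s) with empty profiles", sum(empty)),
            call. = FALSE)
    profiles <- profiles[!empty]
  }
  structure(profiles[order(names(profiles))], source_graph = source_graph,
            class = "phenotype_profiles")
}

#' Union of profiles across sources
#'
#' Per-disease set union, used to derive the enriched (merged) profile from
#' knowledge-base and mined profiles.
#'
#' @param ... `phenotype_profiles` objects.
#' @param source_graph label for the result.
#' @return a `phenotype_profiles` object.
#' @export
merge_profiles <- function(..., source_graph = "merged") {
  inputs <- list(...)
  ids <- sort(unique(unlist(lapply(inputs, names))))
  profiles <- lapply(ids, function(d) {
    sort(unique(unlist(lapply(inputs, function(p) p[[d]]))))
  })
  names(profiles) <- ids
  structure(profiles, source_graph = source_graph, class = "phenotype_profiles")
}

#' Build the weighted disease-disease similarity graph
#'
#' One node per profiled disease; an edge for every unordered pair whose
#' Jaccard similarity strictly exceeds `min_weight` (default 0, so
#' zero-similarity pairs never form edges).
#'
#' @param profiles a `phenotype_profiles` object ([build_profiles()]).
#' @param min_weight edge inclusion threshold in `[0, 1]` (strict).
#' @param disease_labels named character vector (`"rare"`/`"common"`) used
#'   for RD/CD node labels; unknown diseases default to `"rare"`.
#' @return a `disease_similarity_graph`: list with `nodes` (data frame
#'   `disease_id`, `rarity`) and `edges` (data frame `disease_i`,
#'   `disease_j`, `weight`, with `disease_i < disease_j`).
#' @export
build_similarity_graph <- function(profiles, min_weight = 0,
                                   disease_labels = character()) {
  stopifnot(inherits(profiles, "phenotype_profiles"))
  check_probability(min_weight, "min_weight")
  ids <- names(profiles)
  labels <- stats::setNames(as.character(disease_labels),
                            normalize_id(names(disease_labels)))
  nodes <- data.frame(
    disease_id = ids,
    rarity = ifelse(is.na(labels[ids]) | labels[ids] == "rare", "RD", "CD"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(disease_i = character(), disease_j = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(ids) > 1) {
    combos <- utils::combn(ids, 2)
    w <- vapply(seq_len(ncol(combos)), function(k) {
      jaccard(profiles[[combos[1, k]]], profiles[[combos[2, k]]])
    }, numeric(1))
    keep <- w > min_weight
    edges <- data.frame(disease_i = combos[1, keep], disease_j = combos[2, keep],
                        weight = w[keep], stringsAsFactors = FALSE)
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 source_graph = attr(profiles, "source_graph")),
            class = "disease_similarity_graph")
}

#' @export
print.disease_similarity_graph <- function(x, ...) {
  cat(sprintf("<disease_similarity_graph [%s]> %d diseases, %d weighted edges\n",
              x$source_graph %||% "?", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Rank differential-diagnosis candidates for a query disease
#'
#' Neighbours of the query in the similarity graph, in descending order of
#' Jaccard similarity (ties broken by disease id ascending), truncated to the
#' top `k`.
#'
#' @param graph a `disease_similarity_graph`.
#' @param query disease id (normalized before lookup).
#' @param k number of candidates to return (default 15); `Inf` returns all.
#' @return data frame of class `candidate_ranking` with columns `rank`,
#'   `disease_id`, `rarity`, `score`, plus attribute `query`.
#' @export
rank_candidates <- function(graph, query, k = 15) {
  stopifnot(inherits(graph, "disease_similarity_graph"))
  query <- normalize_id(query)
  if (!(query %in% graph$nodes$disease_id)) {
    stop(sprintf("query disease '%s' is not a node of the similarity graph", query),
         call. = FALSE)
  }
  e <- graph$edges
  inc <- e$disease_i == query | e$disease_j == query
  nbr <- ifelse(e$disease_i[inc] == query, e$disease_j[inc], e$disease_i[inc])
  out <- data.frame(disease_id = nbr, score = e$weight[inc], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$disease_id), , drop = FALSE]
  if (is.finite(k)) out <- utils::head(out, k)
  rarity <- stats::setNames(graph$nodes$rarity, graph$nodes$disease_id)
  out <- data.frame(rank = seq_len(nrow(out)), disease_id = out$disease_id,
                    rarity = unname(rarity[out$disease_id]), score = out$score,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "query") <- query
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' Export a disease similarity graph as node-link JSON
#'
#' Writes a deterministic node-link document with the query flagged as the
#' center node, RD/CD labels on every node, and edge weights.
#'
#' @param graph a `disease_similarity_graph`.
#' @param query disease id to flag as center.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_similarity_graph <- function(graph, query, path) {
  stopifnot(inherits(graph, "disease_similarity_graph"))
  query <- normalize_id(query)
  if (!(query %in% graph$nodes$disease_id)) {
    stop(sprintf("query disease '%s' is not a node of the similarity graph", query),
         call. = FALSE)
  }
  nodes <- graph$nodes[order(graph$nodes$disease_id), , drop = FALSE]
  edges <- graph$edges[order(graph$edges$disease_i, graph$edges$disease_j), ,
                       drop = FALSE]
  doc <- list(
    center = query,
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      list(id = nodes$disease_id[i], rarity = nodes$rarity[i],
           center = nodes$disease_id[i] == query)
    }),
    links = lapply(seq_len(nrow(edges)), function(i) {
      list(source = edges$disease_i[i], target = edges$disease_j[i],
           weight = edges$weight[i])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a similarity graph back from node-link JSON
#'
#' Inverse of [export_similarity_graph()].
#'
#' @param path JSON file written by [export_similarity_graph()].
#' @return a `disease_similarity_graph` (the center flag is returned as
#'   attribute `center`).
#' @export
read_similarity_graph <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- data.frame(
    disease_id = vapply(doc$nodes, `[[`, character(1), "id"),
    rarity = vapply(doc$nodes, `[[`, character(1), "rarity"),
    stringsAsFactors = FALSE
  )
  edges <- if (length(doc$links)) {
    data.frame(
      disease_i = vapply(doc$links, `[[`, character(1), "source"),
      disease_j = vapply(doc$links, `[[`, character(1), "target"),
      weight = vapply(doc$links, function(l) as.numeric(l$weight), numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(disease_i = character(), disease_j = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, source_graph = NULL),
            class = "disease_similarity_graph", center = doc$center)
}
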