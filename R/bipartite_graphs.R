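# Disease-phenotype bipartite graphs.
#
# Associations from the knowledge base, from mining, or from their union are
# represented as bipartite graphs with disjoint disease (U) and phenotype (V)
# vertex sets and edges only across sets. Characterization statistics use the
# total vertex count |U| + |V|: density = 2|E| / (|V_total| (|V_total| - 1))
# and average degree = 2|E| / |V_total|, linked by the identity
# average_degree = density * (|V_total| - 1).

#' Construct an association set
#'
#' A deduplicated set of (phenotype, disease) pairs with per-pair provenance
#' and rare/common disease labels. Identifiers are normalized on construction
#' ([normalize_id()]).
#'
#' @param pairs data frame with columns `phenotype_id`, `disease_id` and
#'   optionally `provenance`.
#' @param disease_labels named character vector mapping normalized disease id
#'   to `"rare"` or `"common"`; diseases absent from it get `default_label`.
#' @param provenance label applied to pairs lacking one, conventionally
#'   `"KB"`, `"EMR"`, `"both"` or `"literature"`.
#' @param default_label label for diseases missing from `disease_labels`.
#' @return an `association_set`: data frame (`phenotype_id`, `disease_id`,
#'   `provenance`) with a `disease_labels` attribute.
#' @export
association_set <- function(pairs, disease_labels = character(),
                            provenance = "KB", default_label = "rare") {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0 &&
      !all(c("phenotype_id", "disease_id") %in% names(pairs))) {
    stop("`pairs` needs columns phenotype_id and disease_id", call. = FALSE)
  }
  if (nrow(pairs) == 0) {
    pairs <- data.frame(phenotype_id = character(), disease_id = character(),
                        provenance = character(), stringsAsFactors = FALSE)
  } else {
    pairs$phenotype_id <- normalize_id(pairs$phenotype_id)
    pairs$disease_id <- normalize_id(pairs$disease_id)
    if (is.null(pairs$provenance)) pairs$provenance <- provenance
    dup <- duplicated(pairs[c("phenotype_id", "disease_id")])
    if (any(dup)) {
      message(sprintf("collapsed %d duplicate pair(s)", sum(dup)))
      pairs <- pairs[!dup, , drop = FALSE]
    }
    pairs <- pairs[order(pairs$disease_id, pairs$phenotype_id),
                   c("phenotype_id", "disease_id", "provenance"), drop = FALSE]
    rownames(pairs) <- NULL
  }
  labels <- stats::setNames(as.character(disease_labels),
                            normalize_id(names(disease_labels)))
  need <- setdiff(unique(pairs$disease_id), names(labels))
  labels <- c(labels, stats::setNames(rep(default_label, length(need)), need))
  if (!all(labels %in% c("rare", "common"))) {
    stop_field("disease_labels", "values must be 'rare' or 'common'")
  }
  structure(pairs, disease_labels = labels,
            class = c("association_set", "data.frame"))
}

# Coerce association sets / rule tables / plain frames to a pair data frame.
as_pair_df <- function(x) {
  df <- as.data.frame(x)
  if (!all(c("phenotype_id", "disease_id") %in% names(df))) {
    stop("expected columns phenotype_id and disease_id", call. = FALSE)
  }
  df <- data.frame(phenotype_id = normalize_id(df$phenotype_id),
                   disease_id = normalize_id(df$disease_id),
                   stringsAsFactors = FALSE)
  unique(df)
}

# Rare/common labels attached to an association set (possibly empty).
set_labels <- function(x) attr(x, "disease_labels") %||% character()

#' Build a bipartite disease-phenotype graph from an association set
#'
#' @param assoc an [association_set()] (or data frame of pairs).
#' @param name graph label, e.g. `"KB"`, `"EMR"`, `"merged"`.
#' @return a `bipartite_graph`: list with disease vertex set `U`, phenotype
#'   vertex set `V`, edge data frame `edges` (`phenotype_id`, `disease_id`,
#'   `provenance`), `disease_labels`, and `name`.
#' @export
build_graph <- function(assoc, name = "graph") {
  pairs <- if (inherits(assoc, "association_set")) as.data.frame(assoc)
           else as.data.frame(association_set(assoc))
  U <- sort(unique(pairs$disease_id))
  V <- sort(unique(pairs$phenotype_id))
  clash <- intersect(U, V)
  if (length(clash) > 0) {
    stop(sprintf("identifier(s) appear as both disease and phenotype: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  if (is.null(pairs$provenance)) pairs$provenance <- "KB"
  labels <- if (inherits(assoc, "association_set")) set_labels(assoc) else character()
  need <- setdiff(U, names(labels))
  labels <- c(labels, stats::setNames(rep("rare", length(need)), need))
  structure(
    list(U = U, V = V,
         edges = pairs[order(pairs$disease_id, pairs$phenotype_id), , drop = FALSE],
         disease_labels = labels[names(labels) %in% U],
         name = name),
    class = "bipartite_graph"
  )
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph '%s'> %d diseases, %d phenotypes, %d edges\n",
              x$name, length(x$U), length(x$V), nrow(x$edges)))
  invisible(x)
}

#' Merge two bipartite graphs into an enriched graph
#'
#' Vertex and edge sets are set unions; an edge present in both inputs is
#' relabeled with provenance `"both"`.
#'
#' @param g_kb,g_emr `bipartite_graph` objects; provenance of edges unique to
#'   each input is taken from that input.
#' @param name label of the merged graph.
#' @return a `bipartite_graph`.
#' @export
merge_graphs <- function(g_kb, g_emr, name = "merged") {
  stopifnot(inherits(g_kb, "bipartite_graph"), inherits(g_emr, "bipartite_graph"))
  key <- function(e) paste(e$phenotype_id, e$disease_id, sep = "\r")
  e1 <- g_kb$edges; e2 <- g_emr$edges
  shared <- intersect(key(e1), key(e2))
  e1$provenance[key(e1) %in% shared] <- "both"
  e2 <- e2[!(key(e2) %in% shared), , drop = FALSE]
  edges <- rbind(e1, e2)
  labels <- c(g_kb$disease_labels,
              g_emr$disease_labels[setdiff(names(g_emr$disease_labels),
                                           names(g_kb$disease_labels))])
  build_graph(association_set(edges, disease_labels = labels), name = name)
}

#' Restrict a bipartite graph to a set of diseases
#'
#' Keeps only edges whose disease endpoint is in `keep`; phenotypes left
#' without any edge are dropped (vertex counts are edge-supported).
#'
#' @param g a `bipartite_graph`.
#' @param keep character vector of disease ids (normalized on use); unknown
#'   ids are simply absent.
#' @return a `bipartite_graph`.
#' @export
restrict_to_diseases <- function(g, keep) {
  stopifnot(inherits(g, "bipartite_graph"))
  keep <- normalize_id(keep)
  edges <- g$edges[g$edges$disease_id %in% keep, , drop = FALSE]
  build_graph(association_set(edges, disease_labels = g$disease_labels),
              name = g$name)
}

#' Characterization statistics of a bipartite graph
#'
#' With `n = |U| + |V|` total vertices and `m` edges:
#' `density = 2 m / (n (n - 1))` and `average_degree = 2 m / n` (both 0 for
#' degenerate vertex counts).
#'
#' @param g a `bipartite_graph`.
#' @return a `graph_stats` list: `n_disease`, `n_phenotype`, `n_edges`,
#'   `density`, `average_degree`.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "bipartite_graph"))
  n <- length(g$U) + length(g$V)
  m <- nrow(g$edges)
  structure(
    list(n_disease = length(g$U), n_phenotype = length(g$V), n_edges = m,
         density = if (n < 2) 0 else 2 * m / (n * (n - 1)),
         average_degree = if (n == 0) 0 else 2 * m / n),
    class = "graph_stats"
  )
}

#' Stats table for several graphs
#'
#' One column per graph, rows mirroring the standard characterization report
#' (node counts, edges, density, average degree). `density` and
#' `average_degree` are reported both at full precision and rounded half-up
#' to 3 decimals.
#'
#' @param graphs named list of `bipartite_graph` objects.
#' @return data frame with a `statistic` column and one column per graph.
#' @export
graph_stats_table <- function(graphs) {
  stats_list <- lapply(graphs, graph_stats)
  cols <- lapply(stats_list, function(s) {
    c(s$n_disease, s$n_phenotype, s$n_edges, s$density, s$average_degree,
      round_half_up(s$density, 3), round_half_up(s$average_degree, 3))
  })
  out <- data.frame(
    statistic = c("n_disease_nodes", "n_phenotype_nodes", "n_edges",
                  "density", "average_degree", "density_3dp", "average_degree_3dp"),
    stringsAsFactors = FALSE
  )
  for (nm in names(graphs)) out[[nm]] <- cols[[nm]]
  out
}

#' Top-k diseases by degree
#'
#' @param g a `bipartite_graph`.
#' @param k cutoff (>= 1); fewer rows are returned when the graph has fewer
#'   diseases.
#' @return data frame of class `degree_ranking` with columns `disease_id`,
#'   `rarity` (`RD`/`CD`), `degree`, sorted by (`degree` desc, `disease_id`
#'   asc).
#' @export
top_degree_diseases <- function(g, k = 15) {
  stopifnot(inherits(g, "bipartite_graph"))
  check_count(k, "k", min = 1)
  deg <- table(factor(g$edges$disease_id, levels = g$U))
  out <- data.frame(disease_id = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out$rarity <- ifelse(g$disease_labels[out$disease_id] == "rare", "RD", "CD")
  out <- out[order(-out$degree, out$disease_id), c("disease_id", "rarity", "degree")]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  class(out) <- c("degree_ranking", "data.frame")
  out
}

#' Overlap statistics between two association sets
#'
#' Mirrors the standard enrichment bookkeeping: for diseases, phenotypes and
#' associations it reports the count in each source, the shared count, and
#' the count unique to the second source (`n_b - n_shared`).
#'
#' @param set_a,set_b [association_set()] objects (conventionally the
#'   knowledge base and the mined set).
#' @return data frame with columns `entity`, `n_a`, `n_b`, `n_shared`,
#'   `n_b_only`.
#' @export
association_set_overlap <- function(set_a, set_b) {
  a <- as_pair_df(set_a); b <- as_pair_df(set_b)
  key <- function(df) paste(df$phenotype_id, df$disease_id, sep = "\r")
  row_for <- function(entity, xa, xb) {
    data.frame(entity = entity, n_a = length(xa), n_b = length(xb),
               n_shared = length(intersect(xa, xb)),
               n_b_only = length(xb) - length(intersect(xa, xb)),
               stringsAsFactors = FALSE)
  }
  rbind(
    row_for("disease", unique(a$disease_id), unique(b$disease_id)),
    row_for("phenotype", unique(a$phenotype_id), unique(b$phenotype_id)),
    row_for("association", key(a), key(b))
  )
}

#' Convert a bipartite graph to an igraph object
#'
#' Nodes carry attributes `bipartite` (`"disease"`/`"phenotype"`) and
#' `rarity` (`"RD"`/`"CD"`, `NA` for phenotypes); edges carry `provenance`.
#'
#' @param g a `bipartite_graph`.
#' @return an igraph graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "bipartite_graph"))
  nodes <- data.frame(
    name = c(g$U, g$V),
    bipartite = rep(c("disease", "phenotype"), c(length(g$U), length(g$V))),
    rarity = c(ifelse(g$disease_labels[g$U] == "rare", "RD", "CD"),
               rep(NA_character_, length(g$V))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = g$edges$disease_id, to = g$edges$phenotype_id,
                      provenance = g$edges$provenance, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Write a bipartite graph as GraphML
#'
#' @param g a `bipartite_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Write a bipartite graph as node-link JSON
#'
#' Deterministic key ordering: nodes sorted disease-first then by id, links
#' sorted by (disease, phenotype).
#'
#' @param g a `bipartite_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  nodes <- lapply(c(g$U, g$V), function(id) {
    side <- if (id %in% g$U) "disease" else "phenotype"
    node <- list(id = id, bipartite = side)
    if (side == "disease") {
      node$rarity <- if (g$disease_labels[[id]] == "rare") "RD" else "CD"
    }
    node
  })
  links <- lapply(seq_len(nrow(g$edges)), function(i) {
    list(source = g$edges$disease_id[i], target = g$edges$phenotype_id[i],
         provenance = g$edges$provenance[i])
  })
  jsonlite::write_json(list(name = g$name, nodes = nodes, links = links),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
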