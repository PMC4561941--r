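# Node ids use an unprintable separator so entity names containing
# punctuation can never collide with triple keys.
.sep <- "\u001f"
entity_id <- function(name) paste0("E", .sep, name)
triple_id <- function(s, p, o) paste0("T", .sep, s, .sep, p, .sep, o)

#' Build the directed entity/predicate graph of a corpus
#'
#' Nodes are biomedical entities plus one predicate-instance node per
#' distinct (subject, predicate, object) triple; arcs run
#' subject -> predicate-instance -> object, weighted by the directed
#' co-occurrence count C (number of predication occurrences of the triple).
#' Predicate nodes are instantiated per triple rather than shared per
#' token: a shared token node would create spurious paths between
#' unrelated argument pairs. Entity IDF is computed as
#' `IDF_i = log(D / D_i)` with the natural log.
#'
#' @param corpus A [predication_corpus()].
#' @return Object of class `entity_graph`: list with `nodes` (data frame:
#'   `id`, `kind` in entity/predicate, `label`, `semtypes`), `edges`
#'   (data frame: `from`, `to`, `C`, `subject`, `predicate`, `object`),
#'   `idf` (named numeric, by entity name), `doc_count`.
#' @export
build_graph <- function(corpus) {
  df <- corpus$predications
  if (nrow(df) == 0L) {
    return(structure(list(
      nodes = data.frame(id = character(0), kind = character(0),
                         label = character(0), semtypes = character(0)),
      edges = data.frame(from = character(0), to = character(0), C = integer(0),
                         subject = character(0), predicate = character(0),
                         object = character(0)),
      idf = stats::setNames(numeric(0), character(0)),
      doc_count = 0L), class = "entity_graph"))
  }
  key <- paste(df$subject_name, df$predicate, df$object_name, sep = .sep)
  first <- !duplicated(key)
  triples <- df[first, c("subject_name", "subject_semtypes", "predicate",
                         "object_name", "object_semtypes")]
  triples$C <- as.integer(table(key)[key[first]])
  # entity nodes keep the semtype list of their first appearance
  ent <- rbind(
    data.frame(label = df$subject_name, semtypes = df$subject_semtypes),
    data.frame(label = df$object_name, semtypes = df$object_semtypes))
  ent <- ent[!duplicated(ent$label), , drop = FALSE]
  ent <- ent[order(ent$label, method = "radix"), , drop = FALSE]
  tid <- triple_id(triples$subject_name, triples$predicate, triples$object_name)
  nodes <- rbind(
    data.frame(id = entity_id(ent$label), kind = "entity",
               label = ent$label, semtypes = ent$semtypes),
    data.frame(id = tid, kind = "predicate",
               label = triples$predicate, semtypes = ""))
  rownames(nodes) <- NULL
  edges <- rbind(
    data.frame(from = entity_id(triples$subject_name), to = tid, C = triples$C,
               subject = triples$subject_name, predicate = triples$predicate,
               object = triples$object_name),
    data.frame(from = tid, to = entity_id(triples$object_name), C = triples$C,
               subject = triples$subject_name, predicate = triples$predicate,
               object = triples$object_name))
  rownames(edges) <- NULL
  idf <- log(corpus$doc_count / corpus$doc_freq[ent$label])
  names(idf) <- ent$label
  structure(list(nodes = nodes, edges = edges, idf = idf,
                 doc_count = corpus$doc_count),
            class = "entity_graph")
}

#' @export
print.entity_graph <- function(x, ...) {
  cat(sprintf("<entity_graph> %d entity + %d predicate nodes, %d arcs, %d documents\n",
              sum(x$nodes$kind == "entity"), sum(x$nodes$kind == "predicate"),
              nrow(x$edges), x$doc_count))
  invisible(x)
}

#' Entity names present in a graph
#' @param graph An [build_graph()] result.
#' @export
entity_names <- function(graph) graph$nodes$label[graph$nodes$kind == "entity"]

#' Filter generalist entities by inverse document frequency
#'
#' Removes entity nodes whose IDF falls below a cutoff, together with all
#' incident predicate-instance nodes and arcs; the graph is returned as a
#' new object. Generalist entities ("PATIENTS"-like terms occurring in
#' nearly every document) have IDF near 0 and are removed first. The
#' cutoff is either an explicit IDF `threshold` (nats) or, by default, the
#' `quantile` of the IDF distribution (drop the bottom 5%); quantile
#' cutoffs are invariant to the logarithm base. The seed entity is exempt.
#'
#' @param graph An `entity_graph`.
#' @param threshold Explicit IDF cutoff; entities with `idf < threshold`
#'   are dropped. Overrides `quantile` when non-`NULL`.
#' @param quantile Fraction of lowest-IDF entities to drop (default 0.05).
#' @param seed Optional seed entity name, never removed.
#' @return A filtered `entity_graph`.
#' @export
idf_filter <- function(graph, threshold = NULL, quantile = 0.05, seed = NULL) {
  if (!is.null(threshold)) assert_scalar_number(threshold, "threshold", lower = 0)
  idf <- graph$idf
  if (length(idf) == 0L) return(graph)
  cut <- if (!is.null(threshold)) threshold else
    as.numeric(stats::quantile(idf, quantile, type = 1L))
  drop <- names(idf)[idf < cut]
  if (!is.null(seed)) drop <- setdiff(drop, seed)
  keep_entity <- setdiff(names(idf), drop)
  edges <- graph$edges
  keep_edge <- edges$subject %in% keep_entity & edges$object %in% keep_entity
  edges <- edges[keep_edge, , drop = FALSE]
  keep_ids <- c(entity_id(keep_entity), unique(edges$to[startsWith(edges$to, "T")]),
                unique(edges$from[startsWith(edges$from, "T")]))
  nodes <- graph$nodes[graph$nodes$id %in% keep_ids, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  if (nrow(nodes) == 0L) warning("IDF filter removed the entire graph")
  structure(list(nodes = nodes, edges = edges, idf = idf[keep_entity],
                 doc_count = graph$doc_count),
            class = "entity_graph")
}

# successor adjacency: named list id -> data.frame(to, label), sorted by
# target label then id for deterministic traversal
successors <- function(graph) {
  edges <- graph$edges
  lab <- stats::setNames(graph$nodes$label, graph$nodes$id)
  ord <- order(lab[edges$to], edges$to, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  split(edges$to, factor(edges$from, levels = unique(graph$nodes$id)))
}

#' Enumerate bounded DFS paths from the seed entity
#'
#' All simple directed paths (no repeated entity node) from the seed,
#' emitted at every even depth up to `max_depth`. Depth counts the nodes
#' after the start, so each traversed triple adds 2 (one predicate node,
#' one entity node): depth 4 means two relation hops. Neighbor order is
#' lexicographic, so enumeration is deterministic; results are sorted by
#' depth, then by the joined node labels.
#'
#' @param graph An `entity_graph`.
#' @param seed Seed entity name; must be a (surviving) entity node.
#' @param max_depth Even integer >= 2 (default 4; the practical ceiling is
#'   6, beyond which few new associations appear).
#' @return Object of class `dfs_paths`: list of paths, each a list with
#'   `nodes` (character labels, entity/predicate alternating, starting at
#'   the seed), `node_ids`, `depth`, `terminal` (last entity name).
#' @export
dfs_paths <- function(graph, seed, max_depth = 4) {
  if (max_depth < 2 || max_depth %% 2 != 0) {
    abort_input("`max_depth` must be an even integer >= 2")
  }
  sid <- entity_id(seed)
  if (!sid %in% graph$nodes$id) {
    abort_input(sprintf("seed entity '%s' is not in the graph (was it IDF-filtered out?)",
                        seed), class = "semsum_seed_error")
  }
  succ <- successors(graph)
  lab <- stats::setNames(graph$nodes$label, graph$nodes$id)
  acc <- new.env(parent = emptyenv())
  acc$paths <- list()
  walk <- function(path_ids, visited_entities, depth) {
    if (depth >= max_depth) return(invisible())
    for (pred in succ[[path_ids[length(path_ids)]]] %||% character(0)) {
      for (ent in succ[[pred]] %||% character(0)) {
        name <- lab[[ent]]
        if (name %in% visited_entities) next
        ids <- c(path_ids, pred, ent)
        acc$paths[[length(acc$paths) + 1L]] <- list(
          nodes = unname(lab[ids]), node_ids = ids,
          depth = depth + 2L, terminal = name)
        walk(ids, c(visited_entities, name), depth + 2L)
      }
    }
  }
  walk(sid, seed, 0L)
  paths <- acc$paths
  if (length(paths)) {
    key <- vapply(paths, function(p) paste(p$nodes, collapse = .sep), character(1))
    depth <- vapply(paths, `[[`, integer(1), "depth")
    paths <- paths[order(depth, key, method = "radix")]
  }
  structure(paths, class = "dfs_paths", seed = seed, max_depth = max_depth)
}

#' @export
print.dfs_paths <- function(x, ...) {
  cat(sprintf("<dfs_paths> %d paths from '%s' (max depth %d)\n",
              length(x), attr(x, "seed"), attr(x, "max_depth")))
  for (p in utils::head(x, 10L)) cat(" ", paste(p$nodes, collapse = " → "), "\n")
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Convert an entity graph to igraph
#'
#' Vertex attributes `kind`, `label`, `semtypes`; edge attribute `C`.
#' @param graph An `entity_graph`.
#' @return An [igraph::graph] object (directed).
#' @export
as_igraph <- function(graph) {
  # internal ids carry a control character that XML forbids; export under
  # readable names (entity label, or "subject | predicate | object")
  export_name <- ifelse(graph$nodes$kind == "entity", graph$nodes$label,
                        gsub(.sep, " | ", substring(graph$nodes$id, 3L), fixed = TRUE))
  rename <- stats::setNames(export_name, graph$nodes$id)
  vertices <- data.frame(name = unname(rename[graph$nodes$id]),
                         kind = graph$nodes$kind,
                         label = graph$nodes$label, semtypes = graph$nodes$semtypes)
  edges <- data.frame(from = unname(rename[graph$edges$from]),
                      to = unname(rename[graph$edges$to]),
                      C = graph$edges$C)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Export an entity graph to GraphML or DOT
#'
#' @param graph An `entity_graph`.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_entity_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(graph), path, format = format)
  invisible(path)
}

#' Write DFS paths as TSV
#'
#' One path per row: the node labels joined by an arrow, the depth, and the
#' terminal entity (plus its score when present).
#'
#' @param paths A `dfs_paths` object or list of path records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paths_tsv <- function(paths, path) {
  df <- data.frame(
    path = vapply(paths, function(p) paste(p$nodes, collapse = " → "), character(1)),
    depth = vapply(paths, `[[`, integer(1), "depth"),
    terminal = vapply(paths, `[[`, character(1), "terminal"))
  score <- vapply(paths, function(p) p$score %||% NA_real_, numeric(1))
  if (!all(is.na(score))) df$score <- score
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
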