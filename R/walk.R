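#' Build the lambda-weighted transition matrix of an entity graph
#'
#' Each arc of a triple is weighted by `lambda * C`, where C is the arc's
#' directed co-occurrence count and lambda is the KM coefficient of the
#' triple's (object primary semantic type, predicate) category; arcs of
#' uncategorized triples fall back to `lambda_floor` (the smallest positive
#' KM score, or 1 when no scores are supplied). Rows are normalized to
#' probabilities.
#'
#' Two variants are exposed because the restart mass can sit in two places:
#' * `"restart"` (default): the matrix holds the plain normalized weights
#'   and the restart probability `alpha` is applied inside [random_walk()]
#'   as `x <- alpha * s + (1 - alpha) * t(M) %*% x`.
#' * `"self-loop"`: each row gets `alpha` on the diagonal and its
#'   off-diagonal mass scaled by `1 - alpha`; the walk then iterates
#'   `x <- t(M) %*% x` with no external restart term.
#'
#' Dangling nodes (no outgoing arcs) send their full mass to the restart
#' node when one is given, otherwise to themselves, so rows always sum to 1.
#'
#' @param graph An `entity_graph`.
#' @param km Optional [km_scores()] data frame supplying lambda.
#' @param alpha Restart probability in (0, 1] (default 0.7).
#' @param variant `"restart"` or `"self-loop"`.
#' @param restart_node Optional node label (entity name) receiving the mass
#'   of dangling rows.
#' @param lambda_floor Fallback lambda; default smallest positive `km$km`
#'   (1 when `km` is `NULL` or has no positive score).
#' @param sparse Use a sparse matrix; default automatic (dense up to 2000
#'   nodes). Results are identical within tolerance either way.
#' @return Object of class `transition_matrix`: list with `matrix`
#'   (row-stochastic, node x node), `order` (node ids), `labels`, `kind`
#'   (node kinds), `alpha`, `variant`, `lambda_floor`.
#' @export
transition_matrix <- function(graph, km = NULL, alpha = 0.7,
                              variant = c("restart", "self-loop"),
                              restart_node = NULL, lambda_floor = NULL,
                              sparse = NULL) {
  variant <- match.arg(variant)
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1)
  nodes <- graph$nodes
  if (nrow(nodes) == 0L) abort_input("cannot build a transition matrix from an empty graph")
  n <- nrow(nodes)
  if (is.null(sparse)) sparse <- n > 2000L
  if (is.null(lambda_floor)) {
    pos <- if (!is.null(km)) km$km[km$km > 0] else numeric(0)
    lambda_floor <- if (length(pos)) min(pos) else 1
  }
  edges <- graph$edges
  lambda <- rep(lambda_floor, nrow(edges))
  if (!is.null(km) && nrow(km) && nrow(edges)) {
    # category of a triple = (object primary semtype, predicate); both arcs
    # of the triple share it
    obj_sem <- stats::setNames(primary_semtype(nodes$semtypes), nodes$label)
    key <- paste(obj_sem[edges$object], edges$predicate, sep = "\r")
    km_key <- paste(km$semtype, km$predicate, sep = "\r")
    m <- match(key, km_key)
    hit <- !is.na(m) & km$km[ifelse(is.na(m), 1L, m)] > 0
    lambda[hit] <- km$km[m[hit]]
  }
  idx <- stats::setNames(seq_len(n), nodes$id)
  i <- idx[edges$from]; j <- idx[edges$to]
  w <- lambda * edges$C
  M <- if (sparse) {
    Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  } else {
    out <- matrix(0, n, n)
    for (k in seq_along(i)) out[i[k], j[k]] <- out[i[k], j[k]] + w[k]
    out
  }
  rs <- if (sparse) Matrix::rowSums(M) else rowSums(M)
  dangling <- which(rs == 0)
  if (length(dangling)) {
    tgt <- if (!is.null(restart_node)) {
      t <- idx[entity_id(restart_node)]
      if (is.na(t)) abort_input(sprintf("restart node '%s' not in graph", restart_node))
      t
    } else NA_integer_
    for (d in dangling) {
      M[d, if (is.na(tgt)) d else tgt] <- 1
    }
    rs[dangling] <- 1
  }
  M <- if (sparse) Matrix::Diagonal(x = 1 / rs) %*% M else M / rs
  if (variant == "self-loop") {
    M <- (1 - alpha) * M
    Matrix::diag(M) <- Matrix::diag(M) + alpha
  }
  structure(list(matrix = M, order = nodes$id, labels = nodes$label,
                 kind = nodes$kind, alpha = alpha, variant = variant,
                 lambda_floor = lambda_floor),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d nodes, alpha = %g, variant = %s\n",
              length(x$order), x$alpha, x$variant))
  invisible(x)
}

#' Random walk with restart
#'
#' Iterates `x <- alpha * s + (1 - alpha) * t(M) %*% x` from `x = s`, where
#' `s` is the restart vector (1 at the start node), until the L1 difference
#' between successive iterates drops below `tolerance` or `max_iter` is
#' reached. With a `"self-loop"` transition matrix the restart is already
#' inside M and the iteration is the plain power step `x <- t(M) %*% x`.
#'
#' @param m A [transition_matrix()].
#' @param start Start entity name (or full node id).
#' @param tolerance L1 convergence threshold (default 1e-6).
#' @param max_iter Iteration cap (default 50). Non-convergence is reported,
#'   not an error.
#' @return Object of class `walk_result`: list with `stationary` (named by
#'   node label), `restart_vector`, `iterations`, `converged`, `tolerance`,
#'   `order`, `labels`, `kind`.
#' @export
random_walk <- function(m, start, tolerance = 1e-6, max_iter = 50) {
  sid <- if (start %in% m$order) start else entity_id(start)
  pos <- match(sid, m$order)
  if (is.na(pos)) abort_input(sprintf("start node '%s' not in transition matrix", start))
  n <- length(m$order)
  s <- numeric(n); s[pos] <- 1
  x <- s
  Mt <- Matrix::t(m$matrix)
  alpha <- m$alpha
  restart <- m$variant == "restart"
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x_new <- as.numeric(Mt %*% x)
    if (restart) x_new <- alpha * s + (1 - alpha) * x_new
    if (sum(abs(x_new - x)) < tolerance) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  structure(list(stationary = stats::setNames(x, m$labels), restart_vector = s,
                 iterations = it, converged = converged, tolerance = tolerance,
                 order = m$order, labels = m$labels, kind = m$kind),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("<walk_result> %d nodes, %d iterations, %s\n",
              length(x$stationary), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Rank entities by stationary probability and retain their paths
#'
#' Entity nodes (the seed excluded) are ranked by stationary probability,
#' descending, ties broken by name; the paths whose destination (terminal)
#' entity ranks within the top N are retained, each annotated with its
#' terminal's probability.
#'
#' @param paths A [dfs_paths()] result (paths share the walk's seed).
#' @param walk A [random_walk()] result.
#' @param top_n Number of top entities to keep (default 10).
#' @return Object of class `filtered_relations`: list with `top_entities`
#'   (data frame `rank`, `entity`, `probability`) and `retained_paths`
#'   (list of path records with a `score` element).
#' @export
rank_and_filter <- function(paths, walk, top_n = 10) {
  if (!is.numeric(top_n) || length(top_n) != 1L || is.na(top_n) || top_n <= 0) {
    abort_input("`top_n` must be a positive count")
  }
  seed <- attr(paths, "seed")
  is_entity <- walk$kind == "entity" & walk$labels != (seed %||% "")
  prob <- walk$stationary[is_entity]
  name <- walk$labels[is_entity]
  ord <- order_ranked(as.numeric(prob), rep(0, length(prob)), name)
  ranked <- data.frame(rank = seq_along(ord), entity = name[ord],
                       probability = as.numeric(prob)[ord],
                       stringsAsFactors = FALSE)
  top <- utils::head(ranked, top_n)
  keep <- vapply(paths, function(p) p$terminal %in% top$entity, logical(1))
  retained <- lapply(unclass(paths)[keep], function(p) {
    p$score <- top$probability[match(p$terminal, top$entity)]
    p
  })
  structure(list(top_entities = top, retained_paths = retained),
            class = "filtered_relations")
}

#' @export
print.filtered_relations <- function(x, ...) {
  cat(sprintf("<filtered_relations> top %d entities, %d retained paths\n",
              nrow(x$top_entities), length(x$retained_paths)))
  invisible(x)
}

#' Node-by-node similarity matrix from repeated restart walks
#'
#' Row j is the stationary vector of a random walk restarted at node j; the
#' companion one-step transition matrix is available from
#' [transition_matrix()]. Restart mass keeps every diagonal entry at least
#' `alpha` under the restart variant.
#'
#' @inheritParams transition_matrix
#' @param tolerance,max_iter Passed to [random_walk()].
#' @return A dense numeric matrix, rows/columns named by node label.
#' @export
similarity_matrix <- function(graph, km = NULL, alpha = 0.7,
                              tolerance = 1e-6, max_iter = 50,
                              variant = c("restart", "self-loop")) {
  variant <- match.arg(variant)
  ids <- graph$nodes$id
  S <- matrix(0, length(ids), length(ids),
              dimnames = list(graph$nodes$label, graph$nodes$label))
  for (k in seq_along(ids)) {
    m <- transition_matrix(graph, km, alpha, variant,
                           restart_node = if (graph$nodes$kind[k] == "entity")
                             graph$nodes$label[k] else NULL)
    S[k, ] <- random_walk(m, ids[k], tolerance, max_iter)$stationary
  }
  S
}

#' Write ranked entities as TSV
#' @param filtered A [rank_and_filter()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_entities_tsv <- function(filtered, path) {
  df <- if (is.data.frame(filtered)) filtered else filtered$top_entities
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
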