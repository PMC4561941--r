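#' Pipeline configuration
#'
#' Central set of tunable parameters with the operational defaults: KLD
#' threshold 0.01 bits, restart probability 0.7, walk tolerance 1e-6, at
#' most 50 iterations, DFS depth 4 (6 as the practical ceiling), bottom 5%
#' of entities dropped by IDF, top 10 entities retained after the walk, and
#' genes (`gngm`) as the target semantic type.
#'
#' @param seed_topic Seed concept name (required downstream).
#' @param kld_threshold Minimum per-predicate KLD term, bits.
#' @param alpha Restart probability in (0, 1].
#' @param walk_tolerance L1 convergence threshold.
#' @param walk_max_iter Iteration cap.
#' @param max_depth DFS depth, even (4 or 6).
#' @param idf_quantile Fraction of lowest-IDF entities dropped.
#' @param top_n Entities kept after the walk.
#' @param target_semtypes Semantic types extracted as entities.
#' @param walk_variant `"restart"` or `"self-loop"`.
#' @param top_k KM rank cutoff for salient categories (default `Inf`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed_topic = NULL, kld_threshold = 0.01,
                            alpha = 0.7, walk_tolerance = 1e-6,
                            walk_max_iter = 50, max_depth = 4,
                            idf_quantile = 0.05, top_n = 10,
                            target_semtypes = c("gngm"),
                            walk_variant = c("restart", "self-loop"),
                            top_k = Inf) {
  walk_variant <- match.arg(walk_variant)
  assert_scalar_number(kld_threshold, "kld_threshold")
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1)
  assert_scalar_number(walk_tolerance, "walk_tolerance", lower = 0)
  assert_scalar_number(walk_max_iter, "walk_max_iter", lower = 1)
  assert_scalar_number(idf_quantile, "idf_quantile", lower = 0, upper = 1)
  assert_scalar_number(top_n, "top_n", lower = 1)
  if (max_depth %% 2 != 0 || max_depth < 2) {
    abort_input("`max_depth` must be an even integer >= 2")
  }
  structure(list(seed_topic = seed_topic, kld_threshold = kld_threshold,
                 alpha = alpha, walk_tolerance = walk_tolerance,
                 walk_max_iter = as.integer(walk_max_iter),
                 max_depth = as.integer(max_depth),
                 idf_quantile = idf_quantile, top_n = as.integer(top_n),
                 target_semtypes = target_semtypes,
                 walk_variant = walk_variant, top_k = top_k),
            class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line (YAML-style scalars only; `#` comments
#' and blank lines ignored). Recognized keys are the arguments of
#' [pipeline_config()]; `target_semtypes` may be comma-separated.
#'
#' @param path Path to the config file.
#' @param overrides Named list of values taking precedence over the file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1L]]
      if (length(m) != 3L) {
        abort_input(paste0("cannot parse config line: ", ln),
                    class = "semsum_config_error")
      }
      vals[[m[[2L]]]] <- m[[3L]]
    }
  }
  vals[names(overrides)] <- overrides
  numeric_keys <- c("kld_threshold", "alpha", "walk_tolerance", "walk_max_iter",
                    "max_depth", "idf_quantile", "top_n", "top_k")
  for (k in intersect(names(vals), numeric_keys)) {
    vals[[k]] <- as.numeric(vals[[k]])
  }
  if (!is.null(vals$target_semtypes) && is.character(vals$target_semtypes)) {
    vals$target_semtypes <- trimws(strsplit(vals$target_semtypes, ",")[[1L]])
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort_input(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
                class = "semsum_config_error")
  }
  do.call(pipeline_config, vals)
}

#' Run the hidden-relation discovery stage
#'
#' Graph build, IDF filtering, bounded DFS from the seed, the restart walk
#' and top-N path retention in one call, logging stage counts.
#'
#' @param corpus A [predication_corpus()].
#' @param config A [pipeline_config()] with a non-`NULL` `seed_topic`.
#' @param km Optional [km_scores()] for the arc weights.
#' @param quiet Suppress stage-count messages.
#' @return List with `graph` (filtered), `paths`, `walk`, `filtered`.
#' @export
discover_relations <- function(corpus, config, km = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(config$seed_topic)) abort_input("config$seed_topic is required")
  graph <- build_graph(corpus)
  say("graph: %d nodes, %d arcs", nrow(graph$nodes), nrow(graph$edges))
  graph <- idf_filter(graph, quantile = config$idf_quantile,
                      seed = config$seed_topic)
  say("after IDF filter (bottom %.0f%%): %d nodes, %d arcs",
      100 * config$idf_quantile, nrow(graph$nodes), nrow(graph$edges))
  paths <- dfs_paths(graph, config$seed_topic, config$max_depth)
  say("DFS: %d paths at depth <= %d", length(paths), config$max_depth)
  m <- transition_matrix(graph, km, config$alpha, config$walk_variant,
                         restart_node = config$seed_topic)
  walk <- random_walk(m, config$seed_topic, config$walk_tolerance,
                      config$walk_max_iter)
  say("walk: %d iterations, converged = %s", walk$iterations, walk$converged)
  filtered <- rank_and_filter(paths, walk, config$top_n)
  say("retained %d paths to top-%d entities",
      length(filtered$retained_paths), config$top_n)
  list(graph = graph, paths = paths, walk = walk, filtered = filtered)
}
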