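# quick triple builder for hand-made corpora
tri <- function(doc, s, ssem, p, o, osem) {
  data.frame(doc_id = doc,
             subject_name = s, subject_cui = "", subject_semtypes = ssem,
             predicate = p,
             object_name = o, object_cui = "", object_semtypes = osem,
             stringsAsFactors = FALSE)
}

corpus_of <- function(...) predication_corpus(do.call(rbind, list(...)))

# the SemRep fielded relation record bundled with the package
semrep_example_line <- function() {
  readLines(system.file("extdata", "semrep_example.txt", package = "semsum"),
            warn = FALSE)[[3L]]
}

extdata <- function(...) system.file("extdata", ..., package = "semsum")

# --- independent oracles ----------------------------------------------------

# term-by-term KLD, written as a literal loop over the definition
oracle_kld_terms <- function(p, q) {
  out <- numeric(length(p))
  names(out) <- names(p)
  for (x in names(p)) out[[x]] <- p[[x]] * log2(p[[x]] / q[[x]])
  out
}

# full MI by double loop over a joint matrix (rows = types, cols = predicates)
oracle_mi <- function(joint_matrix) {
  px <- rowSums(joint_matrix)
  py <- colSums(joint_matrix)
  total <- 0
  for (i in seq_len(nrow(joint_matrix))) {
    for (j in seq_len(ncol(joint_matrix))) {
      pxy <- joint_matrix[i, j]
      if (pxy > 0) total <- total + pxy * log2(pxy / (px[[i]] * py[[j]]))
    }
  }
  total
}

random_distribution <- function(k, names = sprintf("P%02d", seq_len(k))) {
  predicate_distribution(stats::setNames(stats::runif(k, 0.05, 1), names))
}

# exhaustive simple-path enumeration through igraph, independent of the
# package's DFS: even path lengths only, keyed by joined labels
oracle_paths <- function(graph, seed, max_depth) {
  ig <- as_igraph(graph)
  all <- igraph::all_simple_paths(ig, from = seed, cutoff = max_depth,
                                  mode = "out")
  lab <- igraph::V(ig)$label
  names(lab) <- igraph::V(ig)$name
  keys <- character(0)
  for (p in all) {
    len <- length(p) - 1L
    if (len >= 2L && len %% 2L == 0L) {
      keys <- c(keys, paste(lab[names(p)], collapse = " / "))
    }
  }
  sort(keys)
}

path_keys <- function(paths) {
  sort(vapply(paths, function(p) paste(p$nodes, collapse = " / "), character(1)))
}

# direct linear-system solve of the restart walk fixed point
oracle_walk_solve <- function(m, start) {
  M <- as.matrix(m$matrix)
  n <- nrow(M)
  s <- numeric(n)
  s[match(if (start %in% m$order) start else paste0("E", "\u001f", start),
          m$order)] <- 1
  alpha <- m$alpha
  x <- solve(diag(n) - (1 - alpha) * t(M), alpha * s)
  stats::setNames(as.numeric(x), m$labels)
}

# random small corpus for property tests
random_corpus <- function(n = 30, n_docs = 6, seed_topic = NULL) {
  ents <- sprintf("X%02d", 1:8)
  sems <- c("gngm", "aapp", "bacs", "cell")
  preds <- c("R1", "R2", "R3")
  rows <- lapply(seq_len(n), function(i) {
    pair <- sample(ents, 2)
    if (!is.null(seed_topic) && stats::runif(1) < 0.5) pair[1] <- seed_topic
    tri(sprintf("D%02d", sample.int(n_docs, 1)),
        pair[1], sample(sems, 1), sample(preds, 1), pair[2], sample(sems, 1))
  })
  predication_corpus(do.call(rbind, rows))
}
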