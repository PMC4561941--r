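two_node_graph <- function() {
  build_graph(corpus_of(tri("d1", "A", "gngm", "r1", "B", "gngm"),
                        tri("d2", "B", "gngm", "r2", "A", "gngm")))
}

test_that("transition rows follow the lambda*C normalization and alpha placement", {
  # one out-arc, self-loop variant: row = {self: alpha, target: 1 - alpha}
  g <- build_graph(corpus_of(tri("d1", "A", "gngm", "r", "B", "gngm")))
  m <- transition_matrix(g, alpha = 0.7, variant = "self-loop")
  M <- as.matrix(m$matrix)
  i <- match("A", m$labels)
  expect_equal(M[i, i], 0.7)
  expect_equal(sum(M[i, ]), 1)
  expect_equal(M[i, m$labels == "r" ], 0.3)
  # uniform lambda, counts 3:1 -> off-diagonal split 0.75 / 0.25
  g2 <- build_graph(corpus_of(
    tri(c("d1", "d2", "d3"), "A", "gngm", "r", "B", "gngm"),
    tri("d4", "A", "gngm", "s", "C", "gngm")))
  m2 <- transition_matrix(g2, alpha = 0.7, variant = "restart")
  M2 <- as.matrix(m2$matrix)
  a <- match("A", m2$labels)
  expect_equal(sort(M2[a, M2[a, ] > 0]), c(0.25, 0.75))
  expect_error(transition_matrix(g2, alpha = 1.5), "alpha")
})

test_that("a mixed-lambda fixture matrix matches independent hand assembly", {
  # A --r--> B (C=2, category gngm/r, km 0.4); A --s--> C (C=1, aapp/s, km 0.1)
  g <- build_graph(corpus_of(
    tri(c("d1", "d2"), "A", "dsyn", "r", "B", "gngm"),
    tri("d3", "A", "dsyn", "s", "C", "aapp")))
  km <- data.frame(semtype = c("gngm", "aapp"), predicate = c("r", "s"),
                   kld = c(1, 1), mi = c(0.4, 0.1), km = c(0.4, 0.1))
  m <- transition_matrix(g, km, alpha = 0.7, variant = "restart")
  M <- as.matrix(m$matrix)
  a <- match("A", m$labels)
  rn <- which(m$labels == "r" & m$kind == "predicate")
  sn <- which(m$labels == "s" & m$kind == "predicate")
  # hand: weights 0.4*2 = 0.8 and 0.1*1 = 0.1, so 8/9 and 1/9
  expect_equal(M[a, rn], 0.8 / 0.9, tolerance = 1e-12)
  expect_equal(M[a, sn], 0.1 / 0.9, tolerance = 1e-12)
  # predicate rows forward the whole mass to the object
  expect_equal(M[rn, match("B", m$labels)], 1)
})

test_that("dangling rows are repaired and every row sums to 1", {
  g <- build_graph(corpus_of(tri("d1", "A", "gngm", "r", "B", "gngm")))
  m <- transition_matrix(g, restart_node = "A")
  M <- as.matrix(m$matrix)
  expect_equal(unname(rowSums(M)), rep(1, nrow(M)))
  b <- match("B", m$labels)
  expect_equal(M[b, match("A", m$labels)], 1)  # dangling B restarts at A
})

test_that("alpha = 1 collapses the walk to the restart vector", {
  m <- transition_matrix(two_node_graph(), alpha = 1, variant = "restart")
  w <- random_walk(m, "A")
  expect_true(w$converged)
  expect_equal(unname(w$stationary[w$labels == "A"]), 1)
})

test_that("the iterate matches the direct linear solve on a symmetric 2-cycle", {
  m <- transition_matrix(two_node_graph(), alpha = 0.7, variant = "restart")
  w <- random_walk(m, "A", tolerance = 1e-10, max_iter = 200)
  expect_true(w$converged)
  expect_equal(unname(w$stationary), unname(oracle_walk_solve(m, "A")),
               tolerance = 1e-6)
  # fixed-point residual within tolerance
  x <- w$stationary
  s <- w$restart_vector
  resid <- sum(abs(x - (0.7 * s + 0.3 * as.numeric(Matrix::t(m$matrix) %*% x))))
  expect_lte(resid, w$tolerance)
  expect_equal(sum(w$stationary), 1, tolerance = 1e-6)
})

test_that("iterative and direct solutions agree on random graphs up to 50 nodes", {
  set.seed(55)
  for (rep in 1:5) {
    corpus <- random_corpus(n = 25, n_docs = 6, seed_topic = "SEED")
    g <- build_graph(corpus)
    m <- transition_matrix(g, alpha = 0.7, restart_node = "SEED")
    w <- random_walk(m, "SEED", tolerance = 1e-6, max_iter = 50)
    expect_lte(length(m$order), 80)
    expect_equal(unname(w$stationary), unname(oracle_walk_solve(m, "SEED")),
                 tolerance = 1e-5)
  }
})

test_that("dense and sparse representations give identical walks", {
  set.seed(66)
  corpus <- random_corpus(n = 30, n_docs = 5, seed_topic = "SEED")
  g <- build_graph(corpus)
  md <- transition_matrix(g, restart_node = "SEED", sparse = FALSE)
  ms <- transition_matrix(g, restart_node = "SEED", sparse = TRUE)
  expect_equal(unname(random_walk(md, "SEED")$stationary),
               unname(random_walk(ms, "SEED")$stationary), tolerance = 1e-9)
})

test_that("raising C into an entity never lowers its stationary probability", {
  base <- corpus_of(tri("d1", "A", "gngm", "r", "B", "gngm"),
                    tri("d2", "A", "gngm", "s", "C", "gngm"))
  boosted <- corpus_of(tri(c("d1", "d5", "d6"), "A", "gngm", "r", "B", "gngm"),
                       tri("d2", "A", "gngm", "s", "C", "gngm"))
  prob_of_B <- function(corpus) {
    m <- transition_matrix(build_graph(corpus), restart_node = "A")
    w <- random_walk(m, "A")
    unname(w$stationary[w$labels == "B"])
  }
  expect_gte(prob_of_B(boosted), prob_of_B(base))
})

test_that("rank_and_filter retains exactly the paths to top-N entities", {
  g <- generate_fixture_graph("chain", size = 5)
  paths <- dfs_paths(g, "N_01", 4)
  m <- transition_matrix(g, restart_node = "N_01")
  w <- random_walk(m, "N_01")
  all_kept <- rank_and_filter(paths, w, top_n = 100)
  expect_equal(length(all_kept$retained_paths), length(paths))
  one <- rank_and_filter(paths, w, top_n = 1)
  expect_true(all(vapply(one$retained_paths, `[[`, character(1), "terminal") ==
                    one$top_entities$entity[1]))
  expect_error(rank_and_filter(paths, w, top_n = 0), "top_n")
  # brute-force filter oracle on a 10-node random fixture
  set.seed(77)
  corpus <- random_corpus(n = 20, n_docs = 4, seed_topic = "SEED")
  g2 <- build_graph(corpus)
  paths2 <- dfs_paths(g2, "SEED", 4)
  w2 <- random_walk(transition_matrix(g2, restart_node = "SEED"), "SEED")
  fr <- rank_and_filter(paths2, w2, top_n = 3)
  keep_names <- fr$top_entities$entity
  manual <- Filter(function(p) p$terminal %in% keep_names, unclass(paths2))
  expect_equal(path_keys(fr$retained_paths), path_keys(manual))
  # ranked entities exclude the seed and are sorted descending
  expect_false("SEED" %in% fr$top_entities$entity)
  expect_true(!is.unsorted(rev(fr$top_entities$probability)))
})

test_that("similarity matrix rows are restart walks with diagonal >= alpha", {
  g <- generate_fixture_graph("two-community", size = 6, rng_seed = 3)
  S <- similarity_matrix(g, alpha = 0.7)
  expect_equal(unname(rowSums(S)), rep(1, nrow(S)), tolerance = 1e-6)
  expect_true(all(diag(S) >= 0.7 - 1e-9))
  # row for an arbitrary node matches an individual walk
  m <- transition_matrix(g, alpha = 0.7,
                         restart_node = g$nodes$label[g$nodes$kind == "entity"][1])
  w <- random_walk(m, g$nodes$id[g$nodes$kind == "entity"][1])
  k <- which(g$nodes$kind == "entity")[1]
  expect_equal(unname(S[k, ]), unname(w$stationary), tolerance = 1e-9)
})

test_that("IDF filtering strictly lowers a generalist hub's final rank", {
  g <- generate_fixture_graph("hub", size = 8)
  corpus <- attr(g, "corpus")
  seed <- "N_02"   # a spoke, exempt from filtering
  rank_of_hub <- function(graph) {
    w <- random_walk(transition_matrix(graph, restart_node = seed), seed)
    is_ent <- w$kind == "entity" & w$labels != seed
    ranked <- w$labels[is_ent][order(-w$stationary[is_ent],
                                     w$labels[is_ent], method = "radix")]
    match("HUB", ranked)
  }
  unfiltered <- rank_of_hub(g)
  filtered <- idf_filter(g, threshold = 1e-9, seed = seed)
  if ("HUB" %in% entity_names(filtered)) {
    expect_gt(rank_of_hub(filtered), unfiltered)
  } else {
    succeed("hub removed outright by the IDF filter")
  }
})
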