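seed_name <- "Carcinoma of bladder"

km_fixture_corpus <- function() {
  corpus_of(
    tri("d1", "TP53 gene", "gngm", "ASSOCIATED_WITH", seed_name, "neop"),
    tri("d1", seed_name, "neop", "ASSOCIATED_WITH", "FGFR3 gene", "gngm"),
    tri("d2", seed_name, "neop", "PART_OF", "Bladder", "tisu"),
    tri("d2", seed_name, "neop", "AFFECTS", "Smoker", "humn"),
    tri("d2", "Aspirin", "phsu", "TREATS", "Headache", "sosy"))
}

test_that("seed predicate distribution counts subject and object mentions", {
  corpus <- km_fixture_corpus()
  p <- seed_predicate_distribution(corpus, seed_name)
  expect_equal(
    stats::setNames(as.numeric(p), names(p))[c("ASSOCIATED_WITH", "PART_OF", "AFFECTS")],
    c(ASSOCIATED_WITH = 0.5, PART_OF = 0.25, AFFECTS = 0.25))
  one <- seed_predicate_distribution(corpus, "Aspirin")
  expect_equal(stats::setNames(as.numeric(one), names(one)), c(TREATS = 1))
  expect_error(seed_predicate_distribution(corpus, "Nonexistent"),
               "seed topic 'Nonexistent' not found", class = "semsum_seed_error")
})

test_that("per-predicate KLD terms match hand arithmetic and vanish at p = q", {
  p <- predicate_distribution(c(A = 0.5, B = 0.5))
  expect_equal(unname(kld_per_predicate(p, p)), c(0, 0))
  q <- predicate_distribution(c(A = 0.25, B = 0.75))
  terms <- kld_per_predicate(p, q)
  expect_equal(terms[["A"]], 0.5)                      # 0.5 * log2(2)
  expect_equal(terms[["B"]], 0.5 * log2(2 / 3))        # approx -0.29248
})

test_that("KLD terms agree with a brute-force evaluation and sum to D(P||Q) >= 0", {
  set.seed(101)
  for (rep in 1:100) {
    k <- sample(3:8, 1)
    p <- random_distribution(k)
    q <- random_distribution(k)
    terms <- kld_per_predicate(p, q)
    oracle <- oracle_kld_terms(stats::setNames(as.numeric(p), names(p)),
                               stats::setNames(as.numeric(q), names(q)))
    expect_equal(terms, oracle, tolerance = 1e-12)
    expect_gte(sum(terms), -1e-12)   # Gibbs inequality
  }
})

test_that("smoothing keeps KLD finite when a seed predicate is absent from Q", {
  p <- predicate_distribution(c(A = 0.5, NEW = 0.5))
  q <- predicate_distribution(c(A = 90, B = 10))
  terms <- kld_per_predicate(p, q)
  expect_true(all(is.finite(terms)))
  # add-one over the union barely moves the big count: Q'(A) = 91/103
  expect_equal(terms[["A"]], 0.5 * log2(0.5 / (91 / 103)))
  expect_equal(terms[["NEW"]], 0.5 * log2(0.5 / (1 / 103)))
  expect_error(kld_per_predicate(p, q, smooth = FALSE), "smoothing is disabled")
})

test_that("MI terms: independence gives 0, diagonal joint gives 0.5 bits per cell", {
  ind <- corpus_of(
    tri("d1", seed_name, "neop", "R1", "G1", "gngm"),
    tri("d1", seed_name, "neop", "R2", "G2", "gngm"),
    tri("d1", seed_name, "neop", "R1", "P1", "aapp"),
    tri("d1", seed_name, "neop", "R2", "P2", "aapp"))
  mi <- mi_pair_scores(seed_joint_distribution(ind, seed_name))
  expect_equal(mi$mi, rep(0, 4))
  diagonal <- corpus_of(
    tri("d1", seed_name, "neop", "R1", "G1", "gngm"),
    tri("d1", seed_name, "neop", "R2", "P1", "aapp"))
  mi2 <- mi_pair_scores(seed_joint_distribution(diagonal, seed_name))
  expect_equal(sort(mi2$mi), c(0.5, 0.5))
})

test_that("MI terms sum to the double-loop oracle MI, which is nonnegative", {
  set.seed(202)
  for (rep in 1:100) {
    corpus <- random_corpus(n = 40, n_docs = 5, seed_topic = "SEED")
    joint <- seed_joint_distribution(corpus, "SEED")
    jm <- as.matrix(stats::xtabs(prob ~ semtype + predicate, joint$joint))
    expect_equal(mutual_information(joint), oracle_mi(jm), tolerance = 1e-12)
    expect_gte(mutual_information(joint), -1e-12)
  }
})

test_that("km = kld * mi, with rank order invariant to positive rescaling of kld", {
  kld <- c(A = 0.5, B = 0.2, C = 0)
  mi <- data.frame(semtype = c("g", "g", "t", "t"),
                   predicate = c("A", "B", "A", "C"),
                   mi = c(0.2, 0.4, 0.05, 0.3))
  scores <- km_scores(kld, mi)
  expect_equal(scores$km[scores$semtype == "g" & scores$predicate == "A"], 0.1)
  expect_equal(scores$km[scores$predicate == "C"], 0)  # annihilation
  rescaled <- km_scores(kld * 7.3, mi)
  expect_equal(paste(rescaled$semtype, rescaled$predicate),
               paste(scores$semtype, scores$predicate))
})

test_that("select_salient applies the KLD threshold and labels salient predications", {
  corpus <- km_fixture_corpus()
  bg <- predicate_distribution(
    c(ASSOCIATED_WITH = 10, PART_OF = 30, AFFECTS = 30, TREATS = 30))
  res <- km_summarize(corpus, seed_name, bg)
  expect_s3_class(res$summary, "salient_summary")
  # every salient predication involves the seed and a kept category
  sal <- res$summary$salient_predications
  kept <- paste(res$summary$selected_categories$semtype,
                res$summary$selected_categories$predicate)
  expect_true(all(paste(sal$other_semtype, sal$predicate) %in% kept))
  # a threshold above every kld empties the selection, with a warning
  expect_warning(
    empty <- select_salient(res$scores, corpus, seed_name, kld_threshold = 99),
    "no .* category survives")
  expect_equal(nrow(empty$selected_categories), 0L)
  expect_equal(nrow(empty$salient_predications), 0L)
  # threshold 0, unbounded top_k: every positive-kld (hence positive-km
  # with positive mi) category is kept
  all_kept <- select_salient(res$scores, corpus, seed_name, kld_threshold = 0)
  pos <- res$scores[res$scores$kld > 0, ]
  expect_true(all(paste(pos$semtype, pos$predicate) %in%
                    paste(all_kept$selected_categories$semtype,
                          all_kept$selected_categories$predicate)))
})

test_that("extract_entities sums category km over supporting predications", {
  scores <- data.frame(semtype = c("gngm", "gngm"),
                       predicate = c("R1", "R2"),
                       kld = c(0.5, 0.4), mi = c(0.06, 0.025),
                       km = c(0.03, 0.01))
  class(scores) <- c("km_scores", "data.frame")
  corpus <- corpus_of(
    tri("d1", "SEED", "neop", "R1", "G1", "gngm"),
    tri("d2", "SEED", "neop", "R2", "G1", "gngm"),
    tri("d2", "SEED", "neop", "R2", "G2", "gngm"))
  summary <- select_salient(scores, corpus, "SEED", kld_threshold = 0.01)
  ents <- extract_entities(summary)
  expect_equal(ents$entity, c("G1", "G2"))
  expect_equal(ents$score, c(0.04, 0.01))
  expect_equal(ents$support, c(2L, 1L))
  # no target-semtype argument -> empty list
  expect_equal(nrow(extract_entities(summary, target_semtypes = "dsyn")), 0L)
})

test_that("extract_entities agrees with a brute-force recount on random corpora", {
  set.seed(303)
  for (rep in 1:10) {
    corpus <- random_corpus(n = 50, n_docs = 6, seed_topic = "SEED")
    bg <- predicate_distribution(c(R1 = 5, R2 = 3, R3 = 2))
    res <- km_summarize(corpus, "SEED", bg, kld_threshold = 0,
                        target_semtypes = c("gngm", "aapp"))
    sal <- res$summary$salient_predications
    sal <- sal[sal$other_semtype %in% c("gngm", "aapp") & sal$other_name != "SEED", ]
    for (i in seq_len(nrow(res$entities))) {
      e <- res$entities$entity[i]
      expect_equal(res$entities$score[i], sum(sal$km[sal$other_name == e]))
      expect_equal(res$entities$support[i], sum(sal$other_name == e))
    }
    expect_true(!is.unsorted(rev(res$entities$score)))
  }
})
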