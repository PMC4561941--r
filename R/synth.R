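#' Default skewed background predicate distribution
#'
#' A Zipf-like (1/rank) distribution over 15 common relation predicates,
#' emulating the long-tailed predicate frequencies of a large corpus-wide
#' extraction.
#'
#' @return A [predicate_distribution()].
#' @export
default_background_predicates <- function() {
  preds <- c("ASSOCIATED_WITH", "PART_OF", "COEXISTS_WITH", "AFFECTS",
             "PREDISPOSES", "CAUSES", "TREATS", "INTERACTS_WITH",
             "LOCATION_OF", "ISA", "DISRUPTS", "STIMULATES", "INHIBITS",
             "PROCESS_OF", "USES")
  predicate_distribution(stats::setNames(1 / seq_along(preds), preds))
}

.default_semtype_weights <- c(gngm = 0.30, aapp = 0.20, bacs = 0.15,
                              dsyn = 0.10, cell = 0.08, tisu = 0.07,
                              neop = 0.05, comd = 0.05)

#' Configuration for the synthetic predication generator
#'
#' The generator emulates the statistical structure of a disease-focused
#' extraction: a corpus-wide background predicate distribution Q, a
#' seed-topic predication subset whose (semantic type, predicate) joint is
#' the product of the semtype weights and Q except for one planted category
#' whose probability is multiplied by `enrichment`, and a set of planted
#' genes attached to the seed through that category.
#'
#' @param n_docs Number of documents (default 50).
#' @param seed_topic Seed disease concept name.
#' @param background_predicates A [predicate_distribution()] (default
#'   [default_background_predicates()]).
#' @param semtype_weights Named sampling weights for argument semantic
#'   types (default 8 UMLS types led by `gngm`).
#' @param planted_category Length-2 character `(semtype, predicate)`;
#'   default `c("gngm", "ASSOCIATED_WITH")`.
#' @param enrichment Multiplicative boost (>= 1) of the planted category's
#'   joint probability (default 5).
#' @param n_planted_genes Number of ground-truth genes (default 10).
#' @param noise_predications_per_doc Background predications per document
#'   (default 6).
#' @param seed_predications_per_doc Seed-topic predications per document
#'   (default 4).
#' @param rng_seed Single integer driving all sampling (default 1).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 50, seed_topic = "Carcinoma of bladder",
                         background_predicates = default_background_predicates(),
                         semtype_weights = .default_semtype_weights,
                         planted_category = c("gngm", "ASSOCIATED_WITH"),
                         enrichment = 5, n_planted_genes = 10,
                         noise_predications_per_doc = 6,
                         seed_predications_per_doc = 4,
                         rng_seed = 1L) {
  assert_scalar_number(n_docs, "n_docs", lower = 1)
  assert_scalar_number(enrichment, "enrichment", lower = 1)
  assert_scalar_number(n_planted_genes, "n_planted_genes", lower = 0)
  if (enrichment > 1 && n_planted_genes < 1) {
    abort_input("enrichment > 1 requires at least one planted gene")
  }
  if (length(planted_category) != 2L) {
    abort_input("`planted_category` must be c(semtype, predicate)")
  }
  if (!planted_category[[1L]] %in% names(semtype_weights)) {
    abort_input("planted semtype must be among `semtype_weights`")
  }
  if (!planted_category[[2L]] %in% names(background_predicates)) {
    abort_input("planted predicate must be in the background distribution")
  }
  structure(list(
    n_docs = as.integer(n_docs), seed_topic = seed_topic,
    background_predicates = background_predicates,
    semtype_weights = semtype_weights / sum(semtype_weights),
    planted_category = as.character(planted_category),
    enrichment = enrichment, n_planted_genes = as.integer(n_planted_genes),
    noise_predications_per_doc = as.integer(noise_predications_per_doc),
    seed_predications_per_doc = as.integer(seed_predications_per_doc),
    rng_seed = as.integer(rng_seed)), class = "synth_config")
}

# fixed vocabulary: planted genes GENE_xxx, noise pools per semtype
synth_entity_pools <- function(config) {
  pools <- list()
  for (st in names(config$semtype_weights)) {
    prefix <- if (st == "gngm") "NGENE" else toupper(st)
    pools[[st]] <- sprintf("%s_%03d", prefix, seq_len(12L))
  }
  pools
}

#' Generate a synthetic predication corpus with planted ground truth
#'
#' Deterministic given `config$rng_seed` (the caller's RNG state is left
#' untouched). Each document carries `noise_predications_per_doc`
#' background triples over random entity pairs and
#' `seed_predications_per_doc` seed-topic triples whose category is drawn
#' from the enriched joint; when the planted category is drawn, the other
#' argument is one of the planted genes with probability 0.8 (otherwise a
#' noise gene, so the planted signal coexists with background gene
#' mentions).
#'
#' @param config A [synth_config()].
#' @return List with `corpus` (a [predication_corpus()]) and `truth`
#'   (list `genes`, `category`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(config$rng_seed)

  pools <- synth_entity_pools(config)
  planted <- sprintf("GENE_%03d", seq_len(config$n_planted_genes))
  q <- as.numeric(config$background_predicates)
  preds <- names(config$background_predicates)
  tw <- config$semtype_weights
  # enriched joint over (semtype, predicate)
  joint <- outer(tw, stats::setNames(q, preds))
  joint[config$planted_category[1L], config$planted_category[2L]] <-
    joint[config$planted_category[1L], config$planted_category[2L]] * config$enrichment
  joint <- joint / sum(joint)
  cells <- which(joint > 0, arr.ind = TRUE)
  cell_prob <- joint[cells]
  all_noise_entities <- unlist(pools, use.names = FALSE)
  noise_semtype <- rep(names(pools), lengths(pools))

  rows <- vector("list", config$n_docs)
  for (d in seq_len(config$n_docs)) {
    doc <- sprintf("DOC_%04d", d)
    out <- list()
    if (config$noise_predications_per_doc > 0L) {
      k <- config$noise_predications_per_doc
      si <- sample.int(length(all_noise_entities), k, replace = TRUE)
      oi <- sample.int(length(all_noise_entities), k, replace = TRUE)
      clash <- oi == si
      oi[clash] <- (oi[clash] %% length(all_noise_entities)) + 1L
      out$noise <- data.frame(
        doc_id = doc,
        subject_name = all_noise_entities[si], subject_cui = "",
        subject_semtypes = noise_semtype[si],
        predicate = sample(preds, k, replace = TRUE, prob = q),
        object_name = all_noise_entities[oi], object_cui = "",
        object_semtypes = noise_semtype[oi])
    }
    if (config$seed_predications_per_doc > 0L) {
      k <- config$seed_predications_per_doc
      drawn <- sample.int(nrow(cells), k, replace = TRUE, prob = cell_prob)
      st <- rownames(joint)[cells[drawn, 1L]]
      pr <- colnames(joint)[cells[drawn, 2L]]
      is_planted_cat <- st == config$planted_category[1L] &
        pr == config$planted_category[2L]
      other <- character(k)
      for (i in seq_len(k)) {
        other[[i]] <- if (is_planted_cat[[i]] && config$n_planted_genes > 0L &&
                          stats::runif(1) < 0.8) {
          planted[sample.int(length(planted), 1L)]
        } else {
          pool <- pools[[st[[i]]]]
          pool[sample.int(length(pool), 1L)]
        }
      }
      out$seed <- data.frame(
        doc_id = doc,
        subject_name = config$seed_topic, subject_cui = "",
        subject_semtypes = "dsyn",
        predicate = pr,
        object_name = other, object_cui = "",
        object_semtypes = st)
    }
    rows[[d]] <- do.call(rbind, out)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  list(corpus = predication_corpus(df),
       truth = list(genes = planted,
                    category = config$planted_category))
}

#' Generate small fixture graphs with known walk behavior
#'
#' * `"chain"`: entities N_1 -> ... -> N_size in a single line of triples.
#' * `"hub"`: one generalist `HUB` entity with an arc to every other node
#'   (maximal out-degree, present in every document, hence IDF 0), plus a
#'   ring among the spokes.
#' * `"two-community"`: two densely connected halves joined by a single
#'   bridge arc, so a restart walk keeps most stationary mass in its own
#'   community.
#'
#' @param kind One of `"chain"`, `"hub"`, `"two-community"`.
#' @param size Number of entity nodes (>= 3).
#' @param rng_seed Integer seed for the randomized fixtures.
#' @return An `entity_graph`; the generating corpus is attached as
#'   attribute `"corpus"`.
#' @export
generate_fixture_graph <- function(kind = c("chain", "hub", "two-community"),
                                   size = 6, rng_seed = 1L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) abort_input(paste0("unknown fixture kind: ", kind[[1L]])))
  assert_scalar_number(size, "size", lower = 3)
  size <- as.integer(size)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(rng_seed)
  tri <- function(doc, s, p, o) data.frame(
    doc_id = doc, subject_name = s, subject_cui = "", subject_semtypes = "gngm",
    predicate = p, object_name = o, object_cui = "", object_semtypes = "gngm")
  nodes <- sprintf("N_%02d", seq_len(size))
  df <- switch(kind,
    chain = do.call(rbind, lapply(seq_len(size - 1L), function(i)
      tri(sprintf("DOC_%03d", i), nodes[i], sprintf("REL_%02d", i), nodes[i + 1L]))),
    hub = {
      spokes <- nodes[-1L]
      hub_arcs <- do.call(rbind, lapply(seq_along(spokes), function(i)
        tri(sprintf("DOC_%03d", i), "HUB", "ASSOCIATED_WITH", spokes[i])))
      # the hub co-occurs in every document; spokes form a sparse ring
      ring <- do.call(rbind, lapply(seq_along(spokes), function(i)
        tri(sprintf("DOC_%03d", i), spokes[i], "AFFECTS",
            spokes[(i %% length(spokes)) + 1L])))
      rbind(hub_arcs, ring)
    },
    `two-community` = {
      half <- split(nodes, rep(1:2, length.out = size))
      intra <- function(members, offset) {
        pairs <- expand.grid(s = members, o = members, stringsAsFactors = FALSE)
        pairs <- pairs[pairs$s != pairs$o, , drop = FALSE]
        take <- sample.int(nrow(pairs), min(2L * length(members), nrow(pairs)))
        do.call(rbind, lapply(seq_along(take), function(k)
          tri(sprintf("DOC_%03d", offset + k),
              pairs$s[take[k]], "INTERACTS_WITH", pairs$o[take[k]])))
      }
      rbind(intra(half[[1L]], 0L), intra(half[[2L]], 100L),
            tri("DOC_200", half[[1L]][1L], "ISA", half[[2L]][1L]))
    })
  corpus <- predication_corpus(df)
  g <- build_graph(corpus)
  attr(g, "corpus") <- corpus
  g
}
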