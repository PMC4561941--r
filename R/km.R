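# Rows of a corpus mentioning the seed topic, with the *other* argument
# (the entity at the opposite end of the triple) resolved. When the seed
# occupies both argument positions the object side is taken as "other";
# see the methods vignette.
seed_rows <- function(corpus, seed, count_duplicates = TRUE) {
  df <- corpus$predications
  hit <- df$subject_name == seed | df$object_name == seed
  if (!any(hit)) {
    nearest <- utils::head(stringi_sort(unique(c(df$subject_name, df$object_name))), 5L)
    abort_input(sprintf("seed topic '%s' not found in corpus; entities include: %s",
                        seed, paste(nearest, collapse = ", ")),
                class = "semsum_seed_error")
  }
  sub <- df[hit, , drop = FALSE]
  seed_is_subject <- sub$subject_name == seed
  out <- data.frame(
    doc_id = sub$doc_id,
    predicate = sub$predicate,
    other_name = ifelse(seed_is_subject, sub$object_name, sub$subject_name),
    other_semtype = primary_semtype(
      ifelse(seed_is_subject, sub$object_semtypes, sub$subject_semtypes)),
    stringsAsFactors = FALSE
  )
  if (!count_duplicates) {
    out <- out[!duplicated(out), , drop = FALSE]
  }
  out
}

#' Predicate distribution of the seed topic's predications
#'
#' Relative frequency of each relation predicate among the predications in
#' which the seed topic appears as subject or object: the distribution P
#' compared against the corpus-wide background Q by the KLD salience score.
#'
#' @param corpus A [predication_corpus()].
#' @param seed Seed-topic concept name (exact, case-sensitive).
#' @param count_duplicates Count repeated identical predications within one
#'   citation separately (default `TRUE`).
#' @return A [predicate_distribution()].
#' @export
seed_predicate_distribution <- function(corpus, seed, count_duplicates = TRUE) {
  rows <- seed_rows(corpus, seed, count_duplicates)
  tab <- table(rows$predicate)
  predicate_distribution(stats::setNames(as.numeric(tab), names(tab)))
}

#' Per-predicate Kullback-Leibler divergence terms
#'
#' For each predicate x in P, the pre-summing KLD term
#' `P(x) * log2(P(x) / Q(x))`, measuring the prevalence of x in the
#' seed-topic distribution P relative to the background Q. Individual terms
#' may be negative; their sum is the divergence `D(P || Q) >= 0`.
#'
#' When a P-predicate is absent from Q, add-one smoothing is applied to Q's
#' counts over the union of the two predicate vocabularies (so large counts
#' are barely distorted and the logarithm stays finite).
#'
#' @param p,q [predicate_distribution()] objects (seed topic, background).
#' @param smooth Apply add-one smoothing when needed (default `TRUE`).
#' @return Named numeric vector of per-predicate terms, in bits.
#' @export
kld_per_predicate <- function(p, q, smooth = TRUE) {
  qx <- stats::setNames(as.numeric(q), names(q))[names(p)]
  qx[is.na(qx)] <- 0
  if (any(qx == 0)) {
    if (!smooth) {
      abort_input(sprintf(
        "background probability is zero for predicate(s) %s and smoothing is disabled",
        paste(names(p)[qx == 0], collapse = ", ")))
    }
    vocab <- union(names(p), names(q))
    counts <- stats::setNames(rep(0, length(vocab)), vocab)
    counts[names(q)] <- attr(q, "counts") %||% as.numeric(q)
    counts <- counts + 1
    qs <- counts / sum(counts)
    qx <- qs[names(p)]
  }
  px <- as.numeric(p)
  stats::setNames(px * log2(px / qx), names(p))
}

#' Joint distribution of argument semantic type and predicate
#'
#' Estimated over the seed topic's predications: for each, the pair
#' (primary semantic type of the non-seed argument, predicate). This is the
#' empirical joint p(x, y) whose pointwise terms feed the MI factor of the
#' KM score.
#'
#' @inheritParams seed_predicate_distribution
#' @return An object of class `joint_type_predicate_distribution`: list with
#'   `joint` (data frame `semtype`, `predicate`, `prob`), `marginal_type`
#'   and `marginal_pred` (named numeric vectors), and `n` (predication count).
#' @export
seed_joint_distribution <- function(corpus, seed, count_duplicates = TRUE) {
  rows <- seed_rows(corpus, seed, count_duplicates)
  tab <- table(rows$other_semtype, rows$predicate)
  prob <- tab / sum(tab)
  idx <- which(prob > 0, arr.ind = TRUE)
  joint <- data.frame(
    semtype = rownames(prob)[idx[, 1L]],
    predicate = colnames(prob)[idx[, 2L]],
    prob = prob[idx],
    stringsAsFactors = FALSE
  )
  joint <- joint[order(joint$semtype, joint$predicate, method = "radix"), ]
  rownames(joint) <- NULL
  structure(list(
    joint = joint,
    marginal_type = stats::setNames(rowSums(prob), rownames(prob)),
    marginal_pred = stats::setNames(colSums(prob), colnames(prob)),
    n = nrow(rows)
  ), class = "joint_type_predicate_distribution")
}

#' Pointwise mutual-information terms per (semantic type, predicate) pair
#'
#' The joint-weighted pointwise term `p(x,y) * log2(p(x,y) / (p(x) p(y)))`
#' for every pair with positive joint mass; pairs with `p(x,y) = 0` are
#' omitted (their term is 0). Summing all terms gives the full mutual
#' information `I(x; y) >= 0` (see [mutual_information()]).
#'
#' @param joint A [seed_joint_distribution()] result.
#' @return Data frame with columns `semtype`, `predicate`, `mi` (bits).
#' @export
mi_pair_scores <- function(joint) {
  j <- joint$joint
  px <- joint$marginal_type[j$semtype]
  py <- joint$marginal_pred[j$predicate]
  data.frame(semtype = j$semtype, predicate = j$predicate,
             mi = j$prob * log2(j$prob / (px * py)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full mutual information between semantic type and predicate
#'
#' @param joint A [seed_joint_distribution()] result.
#' @return `I(x; y)` in bits (sum of all pointwise terms).
#' @export
mutual_information <- function(joint) sum(mi_pair_scores(joint)$mi)

#' KM scores: KLD x MI per (semantic type, predicate) category
#'
#' The KM score of a category is the product of the predicate's KLD salience
#' term and the pair's pointwise MI term. Categories are ranked by KM
#' descending (ties: KLD descending, then semtype, then predicate).
#'
#' @param kld_terms Named vector from [kld_per_predicate()].
#' @param mi_terms Data frame from [mi_pair_scores()].
#' @return Data frame of class `km_scores` with columns `semtype`,
#'   `predicate`, `kld`, `mi`, `km`, sorted by `km` descending.
#' @export
km_scores <- function(kld_terms, mi_terms) {
  kld <- kld_terms[mi_terms$predicate]
  keep <- !is.na(kld)
  out <- data.frame(
    semtype = mi_terms$semtype[keep],
    predicate = mi_terms$predicate[keep],
    kld = as.numeric(kld[keep]),
    mi = mi_terms$mi[keep],
    stringsAsFactors = FALSE
  )
  out$km <- out$kld * out$mi
  ord <- order(-out$km, -out$kld,
               factor(out$semtype, levels = stringi_sort(unique(out$semtype))),
               factor(out$predicate, levels = stringi_sort(unique(out$predicate))),
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("km_scores", "data.frame")
  out
}

#' Select salient categories and predications
#'
#' Keeps the (semantic type, predicate) categories whose predicate KLD term
#' exceeds `kld_threshold` (default 0.01, the operational cut for salient
#' relation predicates) and whose KM rank is at most `top_k`. The salient
#' output is every seed predication whose (other-argument primary semantic
#' type, predicate) matches a kept category.
#'
#' @param scores A [km_scores()] data frame.
#' @param corpus,seed The corpus and seed the scores were computed on.
#' @param kld_threshold Minimum per-predicate KLD term in bits (default 0.01).
#' @param top_k Maximum KM rank to keep (default `Inf`, i.e. all).
#' @param count_duplicates Passed through to the seed-row extraction.
#' @return Object of class `salient_summary`: list with `seed`,
#'   `selected_categories` (km_scores subset), `salient_predications`
#'   (data frame of seed rows with their category), and `n_seed_predications`.
#' @export
select_salient <- function(scores, corpus, seed, kld_threshold = 0.01,
                           top_k = Inf, count_duplicates = TRUE) {
  keep <- scores$kld > kld_threshold & seq_len(nrow(scores)) <= top_k
  selected <- scores[keep, , drop = FALSE]
  rownames(selected) <- NULL
  rows <- seed_rows(corpus, seed, count_duplicates)
  if (nrow(selected) == 0L) {
    warning("no (semantic type, predicate) category survives the thresholds; ",
            "empty salient summary")
    sal <- rows[0L, , drop = FALSE]
    sal$km <- numeric(0)
  } else {
    key <- paste(rows$other_semtype, rows$predicate, sep = "\r")
    sel_key <- paste(selected$semtype, selected$predicate, sep = "\r")
    m <- match(key, sel_key)
    sal <- rows[!is.na(m), , drop = FALSE]
    sal$km <- selected$km[m[!is.na(m)]]
  }
  rownames(sal) <- NULL
  structure(list(seed = seed, selected_categories = selected,
                 salient_predications = sal, n_seed_predications = nrow(rows)),
            class = "salient_summary")
}

#' @export
print.salient_summary <- function(x, ...) {
  cat(sprintf("<salient_summary> seed '%s': %d/%d seed predications in %d categories\n",
              x$seed, nrow(x$salient_predications), x$n_seed_predications,
              nrow(x$selected_categories)))
  invisible(x)
}

#' Extract ranked topic-associated entities from the salient output
#'
#' Every non-seed argument of a salient predication whose primary semantic
#' type is in `target_semtypes` (default `"gngm"`, genes) is scored by the
#' sum of the KM values of its supporting predications' categories;
#' ties are broken by support count, then entity name.
#'
#' @param summary A [select_salient()] result.
#' @param target_semtypes Semantic-type abbreviations to extract
#'   (default `c("gngm")`).
#' @return Data frame with columns `rank`, `entity`, `score`, `support`,
#'   sorted by score descending.
#' @export
extract_entities <- function(summary, target_semtypes = c("gngm")) {
  if (length(target_semtypes) == 0L) {
    abort_input("`target_semtypes` must be non-empty")
  }
  sal <- summary$salient_predications
  sal <- sal[sal$other_semtype %in% target_semtypes &
               sal$other_name != summary$seed, , drop = FALSE]
  if (nrow(sal) == 0L) {
    return(data.frame(rank = integer(0), entity = character(0),
                      score = numeric(0), support = integer(0)))
  }
  score <- tapply(sal$km, sal$other_name, sum)
  support <- tapply(rep(1L, nrow(sal)), sal$other_name, sum)
  entity <- names(score)
  ord <- order_ranked(as.numeric(score), as.numeric(support), entity)
  data.frame(rank = seq_along(ord), entity = entity[ord],
             score = as.numeric(score)[ord], support = as.integer(support)[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' End-to-end KM summarization of a corpus for a seed topic
#'
#' Convenience wrapper: seed predicate distribution, per-predicate KLD
#' against the background, semtype-predicate MI, KM ranking, salient
#' selection and entity extraction in one call.
#'
#' @inheritParams select_salient
#' @param background A [predicate_distribution()] (distribution Q).
#' @param target_semtypes Passed to [extract_entities()].
#' @return List with `scores`, `summary`, `entities`.
#' @export
km_summarize <- function(corpus, seed, background, kld_threshold = 0.01,
                         top_k = Inf, target_semtypes = c("gngm"),
                         count_duplicates = TRUE) {
  p <- seed_predicate_distribution(corpus, seed, count_duplicates)
  kld <- kld_per_predicate(p, background)
  joint <- seed_joint_distribution(corpus, seed, count_duplicates)
  mi <- mi_pair_scores(joint)
  scores <- km_scores(kld, mi)
  summary <- select_salient(scores, corpus, seed, kld_threshold, top_k,
                            count_duplicates)
  entities <- extract_entities(summary, target_semtypes)
  list(scores = scores, summary = summary, entities = entities)
}
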