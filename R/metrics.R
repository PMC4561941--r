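#' Construct a reference standard of genes
#'
#' @param genes Character vector of canonical gene symbols (unique,
#'   non-empty).
#' @param synonyms Optional named character vector mapping alias ->
#'   canonical symbol; every target must be in `genes`.
#' @return Object of class `reference_standard`.
#' @export
reference_standard <- function(genes, synonyms = NULL) {
  genes <- as.character(genes)
  if (any(!nzchar(genes)) || anyDuplicated(genes)) {
    abort_input("reference genes must be non-empty and unique")
  }
  if (!is.null(synonyms)) {
    if (is.null(names(synonyms)) || any(!nzchar(names(synonyms)))) {
      abort_input("`synonyms` must be named alias -> canonical")
    }
    bad <- setdiff(as.character(synonyms), genes)
    if (length(bad)) {
      abort_input(paste0("synonym target(s) not in reference: ",
                         paste(bad, collapse = ", ")))
    }
  }
  structure(list(genes = genes, synonyms = synonyms),
            class = "reference_standard")
}

#' Read a reference standard from plain-text files
#'
#' @param genes_path One gene symbol per line (blank lines ignored).
#' @param synonyms_path Optional two-column TSV `alias<TAB>canonical`.
#' @return A [reference_standard()].
#' @export
read_reference_standard <- function(genes_path, synonyms_path = NULL) {
  genes <- readLines(genes_path, warn = FALSE)
  genes <- trimws(genes[nzchar(trimws(genes))])
  syn <- NULL
  if (!is.null(synonyms_path)) {
    df <- utils::read.delim(synonyms_path, header = FALSE,
                            colClasses = "character", quote = "")
    syn <- stats::setNames(df[[2L]], df[[1L]])
  }
  reference_standard(genes, syn)
}

# map retrieved names through the synonym table (canonical names pass through)
canonicalize <- function(x, reference) {
  syn <- reference$synonyms
  if (is.null(syn)) return(x)
  hit <- match(x, names(syn))
  ifelse(is.na(hit), x, as.character(syn)[hit])
}

#' Confusion counts for a retrieved entity list
#'
#' True positives are retrieved entities in the reference standard or in
#' the separately validated extra set (genes confirmed post hoc, e.g.
#' through GeneRIF review); false negatives are reference genes never
#' retrieved; everything else retrieved is a false positive. Retrieved
#' names are mapped through the synonym table before comparison.
#'
#' @param ranked Character vector of retrieved entities (rank order).
#' @param reference A [reference_standard()].
#' @param validated_extra_tp Extra entities accepted as true positives.
#' @return Named list `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(ranked, reference, validated_extra_tp = character(0)) {
  retrieved <- unique(canonicalize(as.character(ranked), reference))
  positives <- union(reference$genes, validated_extra_tp)
  tp <- sum(retrieved %in% positives)
  list(tp = tp,
       fp = length(retrieved) - tp,
       fn = sum(!reference$genes %in% retrieved))
}

#' Precision, recall and F-score from confusion counts
#'
#' `F = 2PR / (P + R)`, the harmonic mean. Undefined ratios (zero
#' denominator) are reported as `NA`, not 0.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return Named list `precision`, `recall`, `f_score`.
#' @export
precision_recall_f <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort_input("counts must be nonnegative")
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  list(precision = p, recall = r, f_score = f)
}

#' Precision in the top N ranked results
#'
#' @param ranked Character vector in rank order.
#' @param relevant Character vector (or [reference_standard()]) of relevant
#'   entities.
#' @param n Cutoff, >= 1. When `n` exceeds the list length the full list is
#'   used (with a message).
#' @return Fraction of the first `n` entities that are relevant.
#' @export
precision_at_n <- function(ranked, relevant, n) {
  pre <- topn_prefix(ranked, relevant, n)
  sum(pre$hit) / pre$n
}

#' Recall in the top N ranked results
#'
#' @inheritParams precision_at_n
#' @return Fraction of all relevant entities found in the first `n`.
#' @export
recall_at_n <- function(ranked, relevant, n) {
  rel <- relevant_set(relevant)
  pre <- topn_prefix(ranked, relevant, n)
  sum(unique(pre$prefix) %in% rel) / length(rel)
}

relevant_set <- function(relevant) {
  if (inherits(relevant, "reference_standard")) relevant$genes
  else unique(as.character(relevant))
}

topn_prefix <- function(ranked, relevant, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort_input("`n` must be a count >= 1")
  }
  ranked <- as.character(ranked)
  if (inherits(relevant, "reference_standard")) {
    ranked <- canonicalize(ranked, relevant)
  }
  if (n > length(ranked)) {
    message(sprintf("n = %d exceeds list length %d; using the full list",
                    as.integer(n), length(ranked)))
    n <- length(ranked)
  }
  prefix <- ranked[seq_len(n)]
  list(prefix = prefix, hit = prefix %in% relevant_set(relevant), n = n)
}

#' Average precision of a ranked list
#'
#' `AP = (sum_k k / rank_k) / m` over the relevant items actually
#' retrieved, where `rank_k` is the rank of the k-th retrieved relevant
#' item and `m` is the number of retrieved relevant items. Normalizing by
#' retrieved-relevant (rather than the reference-set size) makes AP
#' invariant to relevant items that were never retrieved; with a single
#' topic, MAP equals this AP.
#'
#' @param relevant_ranks Strictly increasing positive integer ranks of the
#'   retrieved relevant items.
#' @return AP as a fraction in (0, 1], or `NA` for an empty rank list.
#' @export
average_precision <- function(relevant_ranks) {
  if (length(relevant_ranks) == 0L) return(NA_real_)
  r <- as.numeric(relevant_ranks)
  if (any(r < 1) || any(diff(r) <= 0)) {
    abort_input("`relevant_ranks` must be strictly increasing positive ranks")
  }
  mean(seq_along(r) / r)
}

#' Full evaluation report for a ranked entity list
#'
#' @param ranked Character vector of retrieved entities in rank order.
#' @param reference A [reference_standard()].
#' @param validated_extra_tp Extra validated true positives (see
#'   [confusion_counts()]).
#' @param n_grid Cutoffs for the P@N / R@N sweeps (default `seq(5, 100, 5)`,
#'   truncated to the list length).
#' @return Object of class `eval_report`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`, `p_at_n`, `r_at_n` (named numeric),
#'   `relevant_ranks`, `average_precision`.
#' @export
evaluate_ranking <- function(ranked, reference, validated_extra_tp = character(0),
                             n_grid = seq(5, 100, 5)) {
  if (length(reference$genes) == 0L) abort_input("empty reference standard")
  cc <- confusion_counts(ranked, reference, validated_extra_tp)
  prf <- precision_recall_f(cc$tp, cc$fp, cc$fn)
  canon <- canonicalize(as.character(ranked), reference)
  positives <- union(reference$genes, validated_extra_tp)
  relevant_ranks <- which(canon %in% positives & !duplicated(canon))
  n_grid <- n_grid[n_grid <= length(ranked)]
  p_at_n <- stats::setNames(
    vapply(n_grid, function(n) precision_at_n(canon, positives, n), numeric(1)),
    n_grid)
  r_at_n <- stats::setNames(
    vapply(n_grid, function(n) recall_at_n(canon, reference$genes, n), numeric(1)),
    n_grid)
  structure(c(cc, prf, list(
    p_at_n = p_at_n, r_at_n = r_at_n,
    relevant_ranks = relevant_ranks,
    average_precision = average_precision(relevant_ranks))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("<eval_report> tp=%d fp=%d fn=%d  P=%s R=%s F=%s  AP=%s\n",
              x$tp, x$fp, x$fn, pct(x$precision), pct(x$recall),
              pct(x$f_score), pct(x$average_precision)))
  invisible(x)
}

#' Write an evaluation report as JSON or TSV
#'
#' @param report An [evaluate_ranking()] result.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    scalars <- c("tp", "fp", "fn", "precision", "recall", "f_score",
                 "average_precision")
    df <- data.frame(metric = scalars,
                     value = vapply(report[scalars], as.numeric, numeric(1)))
    sweep <- data.frame(
      metric = c(paste0("p_at_", names(report$p_at_n)),
                 paste0("r_at_", names(report$r_at_n))),
      value = c(as.numeric(report$p_at_n), as.numeric(report$r_at_n)))
    utils::write.table(rbind(df, sweep), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
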