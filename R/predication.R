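#' Construct a single semantic predication
#'
#' A predication is one subject--predicate--object triple extracted from a
#' document, each argument carrying one or more UMLS semantic-type
#' abbreviations (e.g. `"gngm"` for *Gene or Genome*). The first listed
#' abbreviation is treated as the argument's primary semantic type.
#'
#' @param doc_id Document identifier (e.g. a PMID), coerced to character.
#' @param subject_name,object_name Concept preferred names (non-empty).
#' @param subject_semtypes,object_semtypes Character vectors of semantic-type
#'   abbreviations, or a single comma-joined string; must be non-empty.
#' @param predicate Relation predicate token (uppercase by convention);
#'   must contain no whitespace.
#' @param subject_cui,object_cui Optional concept unique identifiers.
#' @return An object of class `predication` (a named list).
#' @export
predication <- function(doc_id, subject_name, subject_semtypes, predicate,
                        object_name, object_semtypes,
                        subject_cui = "", object_cui = "") {
  join <- function(x) paste(x[nzchar(x)], collapse = ",")
  p <- list(
    doc_id = as.character(doc_id),
    subject_name = as.character(subject_name),
    subject_cui = as.character(subject_cui),
    subject_semtypes = join(as.character(subject_semtypes)),
    predicate = as.character(predicate),
    object_name = as.character(object_name),
    object_cui = as.character(object_cui),
    object_semtypes = join(as.character(object_semtypes))
  )
  if (!nzchar(p$predicate) || grepl("\\s", p$predicate)) {
    abort_input("`predicate` must be a non-empty token with no whitespace")
  }
  if (!nzchar(p$subject_name) || !nzchar(p$object_name)) {
    abort_input("subject and object names must be non-empty")
  }
  if (!nzchar(p$subject_semtypes) || !nzchar(p$object_semtypes)) {
    abort_input("semantic-type lists must be non-empty for both arguments")
  }
  structure(p, class = "predication")
}

corpus_columns <- c("doc_id", "subject_name", "subject_cui", "subject_semtypes",
                    "predicate", "object_name", "object_cui", "object_semtypes")

#' Assemble a predication corpus
#'
#' Bundles an ordered collection of predications with the document
#' bookkeeping needed downstream: the number of distinct documents `D` and
#' the per-entity document frequency `D_i` used by the IDF filter
#' (`IDF_i = log(D / D_i)`).
#'
#' @param predications A data frame with columns `doc_id`, `subject_name`,
#'   `subject_cui`, `subject_semtypes`, `predicate`, `object_name`,
#'   `object_cui`, `object_semtypes` (CUI columns may be empty strings),
#'   or a list of [predication()] objects.
#' @return An object of class `predication_corpus`: a list with elements
#'   `predications` (data frame, row order preserved), `doc_count`
#'   (integer `D`) and `doc_freq` (named integer vector `D_i`, keyed by
#'   entity preferred name, case-sensitive).
#' @export
predication_corpus <- function(predications) {
  if (is.data.frame(predications)) {
    df <- predications
  } else {
    df <- do.call(rbind, lapply(predications, function(p) {
      as.data.frame(unclass(p), stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- empty_predication_frame()
  }
  missing <- setdiff(corpus_columns, names(df))
  if (length(missing)) {
    abort_input(paste0("corpus is missing required columns: ",
                       paste(missing, collapse = ", ")),
                class = "semsum_config_error")
  }
  df <- df[, corpus_columns]
  rownames(df) <- NULL
  doc_count <- length(unique(df$doc_id))
  doc_freq <- compute_doc_freq(df)
  structure(list(predications = df, doc_count = doc_count, doc_freq = doc_freq),
            class = "predication_corpus")
}

empty_predication_frame <- function() {
  as.data.frame(stats::setNames(rep(list(character(0)), length(corpus_columns)),
                                corpus_columns))
}

compute_doc_freq <- function(df) {
  if (nrow(df) == 0L) return(stats::setNames(integer(0), character(0)))
  pairs <- unique(rbind(
    data.frame(entity = df$subject_name, doc = df$doc_id),
    data.frame(entity = df$object_name, doc = df$doc_id)
  ))
  tab <- table(pairs$entity)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.predication_corpus <- function(x, ...) {
  cat(sprintf("<predication_corpus> %d predications, %d documents, %d entities\n",
              nrow(x$predications), x$doc_count, length(x$doc_freq)))
  invisible(x)
}

#' Number of predications in a corpus
#' @param x A `predication_corpus`.
#' @export
n_predications <- function(x) nrow(x$predications)

#' Construct a normalized predicate distribution
#'
#' Relative frequencies of relation predicates, used as the seed-topic
#' distribution P and the corpus-wide background distribution Q of the KLD
#' salience score. Raw counts are retained (as the `"counts"` attribute)
#' because add-one smoothing of Q operates on counts.
#'
#' @param x Named numeric vector: counts or probabilities keyed by predicate.
#' @return Object of class `predicate_distribution`: a named numeric vector
#'   of probabilities summing to 1.
#' @export
predicate_distribution <- function(x) {
  if (length(x) == 0L) abort_input("empty predicate distribution")
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort_input("predicate distribution must be named by predicate")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_input("predicate counts/probabilities must be finite and nonnegative")
  }
  total <- sum(x)
  if (total <= 0) abort_input("all-zero predicate distribution")
  probs <- x / total
  structure(as.numeric(probs),
            names = names(x),
            counts = as.numeric(x),
            class = "predicate_distribution")
}

#' @export
print.predicate_distribution <- function(x, ...) {
  cat(sprintf("<predicate_distribution> %d predicates\n", length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
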