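# Field positions in SemRep full-fielded relation records, 1-based after
# splitting the line on "|". SemRep appends variable trailing metadata, so
# only the positional prefix is interpreted; trailing fields are ignored.
.semrep_pos <- list(
  doc_id = 2L, record_type = 6L,
  subject_cui = 9L, subject_name = 10L, subject_semtypes = 11L,
  predicate = 23L,
  object_cui = 29L, object_name = 30L, object_semtypes = 31L
)

#' Parse one line of SemRep full-fielded output
#'
#' SemRep emits one pipe-delimited record per physical line; records are
#' dispatched on the record-type field ("relation" vs "entity"/"text"/...).
#' Only relation records yield predications.
#'
#' @param line A single line of SemRep fielded output.
#' @param line_number Optional line number, carried on parse errors.
#' @return A [predication()] for relation records, or `NULL` (the skip
#'   marker) for every other record type.
#' @export
parse_semrep_line <- function(line, line_number = NA_integer_) {
  fields <- strsplit(line, "|", fixed = TRUE)[[1L]]
  pos <- .semrep_pos
  if (length(fields) < pos$record_type) return(NULL)
  if (fields[[pos$record_type]] != "relation") return(NULL)
  if (length(fields) < pos$object_semtypes) {
    abort_input(sprintf("malformed relation record at line %s: %d fields, %d required",
                        format(line_number), length(fields), pos$object_semtypes),
                class = "semsum_parse_error")
  }
  grab <- function(i) fields[[i]]
  predicate <- grab(pos$predicate)
  if (!nzchar(predicate)) {
    abort_input(sprintf("relation record with empty predicate at line %s",
                        format(line_number)),
                class = "semsum_parse_error")
  }
  tryCatch(
    predication(
      doc_id = grab(pos$doc_id),
      subject_name = grab(pos$subject_name),
      subject_cui = grab(pos$subject_cui),
      subject_semtypes = strsplit(grab(pos$subject_semtypes), ",", fixed = TRUE)[[1L]],
      predicate = predicate,
      object_name = grab(pos$object_name),
      object_cui = grab(pos$object_cui),
      object_semtypes = strsplit(grab(pos$object_semtypes), ",", fixed = TRUE)[[1L]]
    ),
    semsum_input_error = function(e) {
      abort_input(sprintf("malformed relation record at line %s: %s",
                          format(line_number), conditionMessage(e)),
                  class = "semsum_parse_error")
    }
  )
}

#' Read a SemRep fielded-output file into a predication corpus
#'
#' @param path Path to a SemRep full-fielded output file.
#' @param strict If `FALSE` (default), malformed relation lines are skipped
#'   and a single warning reports how many were dropped; if `TRUE`, the
#'   first malformed line aborts the read. Non-relation records are always
#'   skipped silently.
#' @return A [predication_corpus()].
#' @export
read_semrep <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  preds <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    p <- tryCatch(parse_semrep_line(lines[[i]], i),
                  semsum_parse_error = function(e) {
                    if (strict) stop(e)
                    structure(conditionMessage(e), class = "semsum_skip")
                  })
    if (inherits(p, "semsum_skip")) bad <- bad + 1L else preds[[i]] <- p
  }
  if (bad > 0L) {
    warning(sprintf("skipped %d malformed relation line(s) in %s", bad, path))
  }
  predication_corpus(Filter(Negate(is.null), preds))
}

triple_required_cols <- c("doc_id", "subject_name", "subject_semtypes",
                          "predicate", "object_name", "object_semtypes")

#' Read a simplified triple TSV into a predication corpus
#'
#' The triple dialect is a header-ed tab-separated table with columns
#' `doc_id`, `subject_name`, `subject_semtypes` (comma-joined), `predicate`,
#' `object_name`, `object_semtypes`, and optional `subject_cui` /
#' `object_cui`. Row order is preserved.
#'
#' @param path Path to the TSV file.
#' @return A [predication_corpus()]; an empty file (header only) yields an
#'   empty corpus with `doc_count` 0.
#' @export
read_triples_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = TRUE)
  missing <- setdiff(triple_required_cols, names(df))
  if (length(missing)) {
    abort_input(paste0("triple TSV ", path, " is missing required column(s): ",
                       paste(missing, collapse = ", ")),
                class = "semsum_config_error")
  }
  if (is.null(df$subject_cui)) df$subject_cui <- rep("", nrow(df))
  if (is.null(df$object_cui)) df$object_cui <- rep("", nrow(df))
  predication_corpus(df)
}

#' Write a predication corpus to the simplified triple TSV dialect
#'
#' @param corpus A [predication_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triples_tsv <- function(corpus, path) {
  utils::write.table(corpus$predications, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Load a background predicate distribution
#'
#' Reads the corpus-wide predicate distribution Q (the stand-in for a
#' SemRep-wide predicate frequency table) from a two-column TSV
#' `predicate<TAB>count` (or probability). Counts are normalized to
#' relative frequencies; raw values are kept for add-one smoothing.
#'
#' @param path Path to the two-column TSV (header optional; a non-numeric
#'   second field on line 1 is treated as a header).
#' @return A [predicate_distribution()].
#' @export
read_background_distribution <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) {
    abort_input("background distribution must have two columns: predicate, count",
                class = "semsum_config_error")
  }
  if (is.na(suppressWarnings(as.numeric(df[1L, 2L])))) df <- df[-1L, , drop = FALSE]
  counts <- suppressWarnings(as.numeric(df[[2L]]))
  if (any(is.na(counts))) {
    abort_input("non-numeric count in background distribution",
                class = "semsum_config_error")
  }
  predicate_distribution(stats::setNames(counts, df[[1L]]))
}
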