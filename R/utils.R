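`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
abort_input <- function(msg, class = "semsum_input_error", ...) {
  stop(structure(
    class = c(class, "semsum_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort_input(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

#' Deterministic rank ordering used throughout the package
#'
#' Orders by `score` descending, then `support` descending, then `name`
#' ascending (C locale), so every ranked output is reproducible.
#' @noRd
order_ranked <- function(score, support, name) {
  name <- factor(name, levels = stringi_sort(unique(name)))
  order(-score, -support, name, method = "radix")
}

# locale-independent sort (radix = C collation)
stringi_sort <- function(x) sort(x, method = "radix")

# primary semantic type = first abbreviation of a comma-joined list
primary_semtype <- function(semtypes) {
  vapply(strsplit(semtypes, ",", fixed = TRUE),
         function(s) if (length(s)) s[[1L]] else NA_character_,
         character(1L))
}
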