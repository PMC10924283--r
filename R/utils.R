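`%||%` <- function(x, y) if (is.null(x)) y else x

# Condition helper: all package errors carry a subclass so callers can
# distinguish e.g. a malformed document from an unresolved range.
pkb_stop <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(subclass, "pkb_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

pkb_warn <- function(subclass, message, ...) {
  warning(structure(
    class = c(subclass, "pkb_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# CURIE syntax: upper-case prefix, non-empty local part, single colon split.
CURIE_REGEX <- "^[A-Z][A-Z0-9_.]*:[^[:space:]]+$"

curie_prefix <- function(curie) sub(":.*$", "", curie)
curie_local <- function(curie) sub("^[^:]*:", "", curie)

is_curie <- function(x) grepl(CURIE_REGEX, x)

# Upper-camel-case label for placeholders / blank nodes.
camel_label <- function(x) {
  words <- strsplit(gsub("[^[:alnum:] ]+", " ", x), "[[:space:]]+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) return("Node")
  paste0(toupper(substring(words, 1L, 1L)), substring(words, 2L), collapse = "")
}

empty_df <- function(...) {
  cols <- list(...)
  structure(
    lapply(cols, function(type) vector(type, 0L)),
    names = names(cols),
    class = "data.frame",
    row.names = integer(0)
  )
}
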