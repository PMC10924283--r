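# Value constructors for extracted instance trees.
#
# An instance holds, per attribute, either a single value or a list of
# values (multivalued attributes always hold a list, possibly empty). A
# value is one of:
#   * a literal (plain atomic vector of length 1),
#   * a pkb_mention   -- a span awaiting grounding (class-reference or
#                        value-set range),
#   * a pkb_pending   -- a span awaiting recursive extraction (inlined
#                        class range),
#   * a pkb_grounded  -- a grounded vocabulary reference (CURIE),
#   * a pkb_placeholder -- an ungroundable span rendered with blank-node
#                        syntax,
#   * a nested pkb_instance.

#' Construct an (empty) instance of a schema class
#'
#' @param schema A `pkb_schema`.
#' @param class Class name.
#' @return A `pkb_instance` with one slot per attribute: an empty list for
#'   multivalued attributes, `NULL` otherwise.
#' @export
instance_node <- function(schema, class) {
  cls <- schema_class(schema, class)
  values <- lapply(cls$attributes, function(att) {
    if (att$multivalued) list() else NULL
  })
  names(values) <- names(cls$attributes)
  structure(list(class = class, values = values), class = "pkb_instance")
}

mention <- function(span, target_class) {
  structure(list(span = span, target = target_class), class = "pkb_mention")
}

pending_instance <- function(text, target_class) {
  structure(list(text = text, target = target_class), class = "pkb_pending")
}

#' Grounded and placeholder values
#'
#' `grounded_ref()` represents a span grounded to a vocabulary identifier;
#' `placeholder()` a span that could not be grounded and is rendered with RDF
#' blank-node syntax (`_:Label`).
#'
#' @param curie Grounded identifier, `PREFIX:localid` with upper-case prefix.
#' @param label The lexicon label that matched.
#' @param span The original text span being grounded.
#' @param kind `"exact"` when the lexicon label equals the span verbatim,
#'   `"normalized"` otherwise (case folding, whitespace collapse, fallback
#'   truncation).
#' @return A `pkb_grounded` / `pkb_placeholder` value.
#' @export
grounded_ref <- function(curie, label, span = label, kind = "exact") {
  stopifnot(is_curie(curie))
  structure(
    list(curie = curie, label = label, span = span,
         prefix = curie_prefix(curie), kind = kind),
    class = "pkb_grounded"
  )
}

#' @rdname grounded_ref
#' @export
placeholder <- function(label, span = label) {
  structure(list(label = label, span = span), class = "pkb_placeholder")
}

is_empty_value <- function(v) {
  is.null(v) || (is.list(v) && !is.object(v) && length(v) == 0L)
}

# Canonical plain-list projection used for equality and JSON rendering.
# Provenance attributes (skip records, conflicts) are dropped.
value_plain <- function(v) {
  if (inherits(v, "pkb_instance")) {
    return(instance_plain(v))
  }
  if (inherits(v, "pkb_grounded")) {
    return(list(id = v$curie, label = v$label))
  }
  if (inherits(v, "pkb_placeholder")) {
    return(list(id = paste0("_:", v$label)))
  }
  if (inherits(v, "pkb_mention")) {
    return(list(mention = v$span, class = v$target))
  }
  if (inherits(v, "pkb_pending")) {
    return(list(pending = v$text, class = v$target))
  }
  v
}

instance_plain <- function(inst) {
  out <- list(`@type` = inst$class)
  for (an in names(inst$values)) {
    v <- inst$values[[an]]
    if (is_empty_value(v)) next
    out[[an]] <- if (is.list(v) && !is.object(v)) {
      lapply(v, value_plain)
    } else {
      value_plain(v)
    }
  }
  out
}

#' Compare two instance trees for structural equality
#'
#' Equality is over the canonical projection (class, populated attributes,
#' values including grounded CURIEs and labels); parse provenance attached as
#' attributes is ignored.
#'
#' @param a,b `pkb_instance` objects.
#' @return `TRUE` or `FALSE`.
#' @export
instance_identical <- function(a, b) {
  identical(instance_plain(a), instance_plain(b))
}

#' Ungrounded skeleton of an instance tree
#'
#' Projects an instance to plain nested lists of scalars: grounded values
#' become their CURIEs, placeholders their `_:Label` form, mentions and
#' pending values their spans. This is the shape the rendered YAML re-parses
#' to under a standard YAML parser (label comments are stripped as comments).
#'
#' @param inst A `pkb_instance`.
#' @return A named list keyed by populated attribute names.
#' @export
instance_skeleton <- function(inst) {
  proj <- function(v) {
    if (inherits(v, "pkb_instance")) return(instance_skeleton(v))
    if (inherits(v, "pkb_grounded")) return(v$curie)
    if (inherits(v, "pkb_placeholder")) return(paste0("_:", v$label))
    if (inherits(v, "pkb_mention")) return(v$span)
    if (inherits(v, "pkb_pending")) return(v$text)
    v
  }
  out <- list()
  for (an in names(inst$values)) {
    v <- inst$values[[an]]
    if (is_empty_value(v)) next
    out[[an]] <- if (is.list(v) && !is.object(v)) lapply(v, proj) else proj(v)
  }
  out
}

#' @export
print.pkb_instance <- function(x, ...) {
  cat(render_instance(x, format = "yaml"))
  invisible(x)
}

#' @export
print.pkb_grounded <- function(x, ...) {
  cat(sprintf("<grounded %s ## %s (%s match of '%s')>\n",
              x$curie, x$label, x$kind, x$span))
  invisible(x)
}

#' @export
print.pkb_placeholder <- function(x, ...) {
  cat(sprintf("<placeholder _:%s for '%s'>\n", x$label, x$span))
  invisible(x)
}
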