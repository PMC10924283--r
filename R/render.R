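#' Render an extracted instance tree as YAML or JSON
#'
#' The YAML form follows the conventional extraction-output shape: the
#' document opens with the class name as a header, each populated attribute
#' is an `attribute: value` pair, multivalued values are hyphen-prefixed
#' list elements, nested inlined instances are indented blocks, grounded
#' values are written as the CURIE followed by the human-readable label
#' after a `##` comment (`FOODON:03301844 ## garlic powder`), and
#' placeholders use RDF blank-node syntax (`_:ChoppedOnion`). Because the
#' label is a YAML comment, a standard YAML parser reads the grounded value
#' back as the bare CURIE.
#'
#' The JSON form is the canonical plain projection (`@type` plus populated
#' attributes; grounded values as `{"id": ..., "label": ...}` objects) and
#' is a fixed point under parse-and-re-render.
#'
#' @param x A `pkb_result` or `pkb_instance`.
#' @param format `"yaml"` or `"json"`.
#' @return Document text.
#' @export
render_instance <- function(x, format = c("yaml", "json")) {
  format <- match.arg(format)
  inst <- if (inherits(x, "pkb_result")) x$instance else x
  stopifnot(inherits(inst, "pkb_instance"))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(instance_plain(inst),
                                         auto_unbox = TRUE, pretty = TRUE,
                                         digits = NA)))
  }
  lines <- c(paste0(inst$class, ":"), render_yaml_attrs(inst, indent = 2L))
  paste0(paste(lines, collapse = "\n"), "\n")
}

render_yaml_scalar <- function(v) {
  if (inherits(v, "pkb_grounded")) return(paste0(v$curie, " ## ", v$label))
  if (inherits(v, "pkb_placeholder")) return(paste0("_:", v$label))
  if (inherits(v, "pkb_mention")) return(v$span)
  if (inherits(v, "pkb_pending")) return(v$text)
  as.character(v)
}

render_yaml_attrs <- function(inst, indent) {
  pad <- strrep(" ", indent)
  out <- character()
  for (an in names(inst$values)) {
    v <- inst$values[[an]]
    if (is_empty_value(v)) next
    if (is.list(v) && !is.object(v)) {
      out <- c(out, paste0(pad, an, ":"))
      for (el in v) {
        if (inherits(el, "pkb_instance")) {
          block <- render_yaml_attrs(el, indent = 0L)
          block <- paste0(strrep(" ", indent + 4L), block)
          block[1L] <- paste0(pad, "  - ", sub("^[[:space:]]*", "", block[1L]))
          out <- c(out, block)
        } else {
          out <- c(out, paste0(pad, "  - ", render_yaml_scalar(el)))
        }
      }
    } else if (inherits(v, "pkb_instance")) {
      out <- c(out, paste0(pad, an, ":"),
               render_yaml_attrs(v, indent = indent + 2L))
    } else {
      out <- c(out, paste0(pad, an, ": ", render_yaml_scalar(v)))
    }
  }
  out
}

#' Project an extraction result to an RDF instance graph
#'
#' One node per instance (a blank node unless an identifier attribute is
#' populated), one `rdf:type` assertion per node, and one triple per
#' populated attribute-value pair. Grounded values become IRIs via the
#' schema's prefix declarations; placeholders become blank nodes; literals
#' are typed by their primitive range. Attribute and class IRIs are minted
#' under the schema's own declared prefix when one matching the schema name
#' exists, otherwise under `urn:x-schema:<name>#`.
#'
#' @param result A `pkb_result` or `pkb_instance`.
#' @param schema The `pkb_schema` the instance conforms to; every prefix
#'   used by a grounded value must be declared, otherwise an export error
#'   naming the prefix is raised.
#' @return A `pkb_rdf` object: list with `triples` (data frame `subject`,
#'   `predicate`, `object`, `object_kind` in iri/blank/literal, `datatype`)
#'   and `prefixes`.
#' @seealso [write_turtle()]
#' @export
export_rdf <- function(result, schema) {
  inst <- if (inherits(result, "pkb_result")) result$instance else result
  stopifnot(inherits(inst, "pkb_instance"), inherits(schema, "pkb_schema"))
  base <- if (schema$name %in% names(schema$prefixes)) {
    function(local) paste0(schema$name, ":", local)
  } else {
    function(local) paste0("urn:x-schema:", schema$name, "#", local)
  }
  env <- new.env(parent = emptyenv())
  env$triples <- list()
  env$counter <- 0L
  emit <- function(s, p, o, kind, datatype = NA_character_) {
    env$triples[[length(env$triples) + 1L]] <- data.frame(
      subject = s, predicate = p, object = o, object_kind = kind,
      datatype = datatype, stringsAsFactors = FALSE
    )
  }
  check_prefix <- function(curie) {
    pfx <- curie_prefix(curie)
    if (!pfx %in% names(schema$prefixes)) {
      pkb_stop("pkb_export_error",
               sprintf("prefix '%s' is not declared in the schema", pfx))
    }
    curie
  }
  node_id <- function(node) {
    cls <- schema$classes[[node$class]]
    for (an in names(cls$attributes)) {
      if (cls$attributes[[an]]$identifier && !is_empty_value(node$values[[an]])) {
        v <- node$values[[an]]
        idv <- if (inherits(v, "pkb_grounded")) v$curie else as.character(v)
        if (is_curie(idv)) return(check_prefix(idv))
      }
    }
    env$counter <- env$counter + 1L
    paste0("_:n", env$counter)
  }
  walk <- function(node) {
    subj <- node_id(node)
    emit(subj, "rdf:type", base(node$class), "iri")
    cls <- schema$classes[[node$class]]
    for (an in names(node$values)) {
      v <- node$values[[an]]
      if (is_empty_value(v)) next
      pred <- base(an)
      vals <- if (is.list(v) && !is.object(v)) v else list(v)
      rng <- resolve_range(schema, cls$attributes[[an]])
      for (el in vals) {
        if (inherits(el, "pkb_instance")) {
          child <- walk(el)
          emit(subj, pred, child, if (startsWith(child, "_:")) "blank" else "iri")
        } else if (inherits(el, "pkb_grounded")) {
          emit(subj, pred, check_prefix(el$curie), "iri")
        } else if (inherits(el, "pkb_placeholder")) {
          emit(subj, pred, paste0("_:", el$label), "blank")
        } else if (inherits(el, "pkb_mention") || inherits(el, "pkb_pending")) {
          emit(subj, pred, if (inherits(el, "pkb_mention")) el$span else el$text,
               "literal", "xsd:string")
        } else {
          dt <- if (is.logical(el)) "xsd:boolean"
          else if (is.integer(el)) "xsd:integer"
          else if (is.numeric(el)) "xsd:decimal"
          else "xsd:string"
          emit(subj, pred, as.character(el), "literal", dt)
        }
      }
    }
    subj
  }
  walk(inst)
  triples <- do.call(rbind, env$triples)
  prefixes <- c(
    schema$prefixes,
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    xsd = "http://www.w3.org/2001/XMLSchema#"
  )
  structure(list(triples = triples, prefixes = prefixes,
                 schema_name = schema$name),
            class = "pkb_rdf")
}

#' Serialize an RDF instance graph as Turtle
#'
#' @param x A `pkb_rdf` from [export_rdf()].
#' @param file Optional path; when `NULL` the Turtle text is returned.
#' @return The Turtle document text (invisibly when written to a file).
#' @export
write_turtle <- function(x, file = NULL) {
  stopifnot(inherits(x, "pkb_rdf"))
  used_pfx <- unique(unlist(lapply(
    c(x$triples$subject, x$triples$predicate,
      x$triples$object[x$triples$object_kind == "iri"]),
    function(t) {
      if (startsWith(t, "_:") || grepl("^urn:", t) || grepl("^https?:", t)) NULL
      else curie_prefix(t)
    }
  )))
  used_pfx <- union(used_pfx, "xsd")
  header <- vapply(sort(used_pfx), function(p) {
    sprintf("@prefix %s: <%s> .", p, x$prefixes[[p]])
  }, character(1L))
  term <- function(t, kind = "iri", datatype = NA_character_) {
    if (kind == "literal") {
      lit <- paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", t)), '"')
      if (!is.na(datatype) && datatype != "xsd:string") {
        lit <- paste0(lit, "^^", datatype)
      }
      return(lit)
    }
    if (startsWith(t, "_:")) return(t)
    if (grepl("^urn:", t) || grepl("^https?:", t)) return(paste0("<", t, ">"))
    t
  }
  body <- vapply(seq_len(nrow(x$triples)), function(i) {
    r <- x$triples[i, ]
    sprintf("%s %s %s .", term(r$subject), term(r$predicate),
            term(r$object, r$object_kind, r$datatype))
  }, character(1L))
  doc <- paste0(paste(c(header, "", body), collapse = "\n"), "\n")
  if (is.null(file)) return(doc)
  writeLines(doc, file, sep = "")
  invisible(doc)
}

#' @export
print.pkb_rdf <- function(x, ...) {
  cat(sprintf("<RDF instance graph: %d triples (schema '%s')>\n",
              nrow(x$triples), x$schema_name))
  invisible(x)
}
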