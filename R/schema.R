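#' Knowledge schema construction and loading
#'
#' A knowledge schema is a set of named classes, each with an ordered list of
#' typed attributes, that constrains the shape of instances extracted from
#' text. Attribute ranges are primitives (`string`, `number`, `boolean`),
#' other classes (inlined/embedded or referenced), or named value sets.
#' Classes representing named entities may additionally carry identifier
#' prefix constraints (`id_prefixes`, e.g. `"FOODON"`) and a value set
#' (`values_from`) restricting which vocabulary terms a grounded value may
#' take.
#'
#' Schema documents are YAML in a small LinkML-like dialect: top-level keys
#' `name`, `entry_class`, `prefixes`, `value_sets` and `classes`; per-class
#' keys `attributes`, `id_prefixes`, `values_from`, `named_entity`; per
#' attribute `range`, `multivalued`, `inlined`, `identifier`, `prompt` (also
#' accepted under `annotations: {prompt: ...}`). A bare string attribute
#' value is shorthand for `range`.
#'
#' @param document Path to a schema document, or the document text itself.
#' @return A `pkb_schema` object.
#' @examples
#' s <- recipe_schema()
#' names(s$classes)
#' @seealso [validate_schema()], [resolve_range()], [schema_to_yaml()]
#' @export
load_schema <- function(document) {
  if (!is_string(document)) {
    pkb_stop("pkb_malformed_document", "schema document must be a single string (path or text)")
  }
  text <- if (!grepl("\n", document) && file.exists(document)) {
    paste(readLines(document, warn = FALSE), collapse = "\n")
  } else {
    document
  }
  doc <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      pkb_stop("pkb_malformed_document",
               paste0("cannot parse schema document: ", conditionMessage(e)))
    }
  )
  if (!is.list(doc) || is.null(doc$classes) || length(doc$classes) == 0L) {
    pkb_stop("pkb_malformed_document",
             "schema document is empty or lacks a top-level 'classes:' map")
  }
  if (is.null(names(doc$classes)) || any(!nzchar(names(doc$classes)))) {
    pkb_stop("pkb_malformed_document", "every class must be named")
  }

  value_sets <- lapply(names(doc$value_sets %||% list()), function(vn) {
    parse_value_set(vn, doc$value_sets[[vn]])
  })
  names(value_sets) <- names(doc$value_sets %||% list())

  classes <- lapply(names(doc$classes), function(cn) {
    parse_class(cn, doc$classes[[cn]])
  })
  names(classes) <- names(doc$classes)

  schema <- structure(
    list(
      name = doc$name %||% "schema",
      entry_class = doc$entry_class %||% names(classes)[[1L]],
      prefixes = unlist(doc$prefixes %||% list()) %||% character(),
      value_sets = value_sets,
      classes = classes
    ),
    class = "pkb_schema"
  )
  if (length(schema$prefixes) == 0L) schema$prefixes <- character()

  check_schema_structure(schema)
  schema
}

parse_value_set <- function(name, spec) {
  if (!is.list(spec)) {
    pkb_stop("pkb_malformed_document",
             sprintf("value set '%s' must be a map", name))
  }
  extensional <- if (!is.null(spec$curies)) as.character(unlist(spec$curies)) else NULL
  intensional <- if (!is.null(spec$source) || !is.null(spec$include)) {
    list(
      source = spec$source %||% NA_character_,
      include = as.character(unlist(spec$include %||% list())),
      exclude = as.character(unlist(spec$exclude %||% list()))
    )
  } else {
    NULL
  }
  if (is.null(extensional) == is.null(intensional)) {
    pkb_stop("pkb_malformed_document",
             sprintf("value set '%s' must be exactly one of extensional ('curies') or intensional ('source'/'include')", name))
  }
  value_set_spec(name, extensional = extensional, intensional = intensional)
}

parse_class <- function(name, body) {
  body <- body %||% list()
  attrs_in <- body$attributes %||% list()
  attrs <- lapply(names(attrs_in) %||% character(), function(an) {
    parse_attribute(name, an, attrs_in[[an]])
  })
  if (length(attrs)) names(attrs) <- names(attrs_in) else attrs <- list()
  class_definition(
    name = name,
    attributes = attrs,
    id_prefixes = as.character(unlist(body$id_prefixes %||% list())),
    values_from = body$values_from,
    named_entity = isTRUE(body$named_entity) ||
      length(body$id_prefixes %||% list()) > 0L ||
      !is.null(body$values_from)
  )
}

parse_attribute <- function(class_name, name, body) {
  if (is_string(body)) body <- list(range = body)
  if (!is.list(body)) {
    pkb_stop("pkb_malformed_document",
             sprintf("attribute %s.%s must be a map or a range string", class_name, name))
  }
  prompt <- body$prompt %||% body$annotations$prompt
  attribute_definition(
    name = name,
    range = body$range %||% "string",
    prompt = prompt,
    multivalued = isTRUE(body$multivalued),
    identifier = isTRUE(body$identifier),
    inlined = isTRUE(body$inlined)
  )
}

#' Programmatic schema constructors
#'
#' Build schema components directly in R, bypassing the YAML dialect. Useful
#' for fixture generators and tests.
#'
#' @param name Identifier of the element.
#' @param classes Named list of `class_definition()` results.
#' @param prefixes Named character vector mapping CURIE prefixes to IRI
#'   expansions.
#' @param entry_class Name of the class extraction starts from (defaults to
#'   the first class).
#' @param value_sets Named list of `value_set_spec()` results.
#' @return `schema_definition()` returns a `pkb_schema`; the others return
#'   the corresponding component objects.
#' @export
schema_definition <- function(name, classes, prefixes = character(),
                              entry_class = NULL, value_sets = list()) {
  schema <- structure(
    list(
      name = name,
      entry_class = entry_class %||% names(classes)[[1L]],
      prefixes = prefixes,
      value_sets = value_sets,
      classes = classes
    ),
    class = "pkb_schema"
  )
  check_schema_structure(schema)
  schema
}

#' @rdname schema_definition
#' @param attributes Named list of `attribute_definition()` results, in
#'   prompt order.
#' @param id_prefixes Character vector of allowed identifier prefixes for
#'   grounded instances of this class.
#' @param values_from Optional name of a value set constraining groundings.
#' @param named_entity Whether leaf values of this class are grounded to
#'   vocabulary identifiers.
#' @export
class_definition <- function(name, attributes = list(), id_prefixes = character(),
                             values_from = NULL, named_entity = FALSE) {
  structure(
    list(
      name = name,
      attributes = attributes,
      id_prefixes = id_prefixes,
      values_from = values_from,
      named_entity = isTRUE(named_entity) || !is.null(values_from)
    ),
    class = "pkb_class"
  )
}

#' @rdname schema_definition
#' @param range Attribute range: `"string"`, `"number"`, `"boolean"`, a class
#'   name, or a value-set name.
#' @param prompt Optional custom prompt text for the attribute; when `NULL`
#'   the prompt is auto-generated from the name (see [auto_prompt()]).
#' @param multivalued Whether the value is a semicolon-delimited list.
#' @param identifier Whether this attribute is the persistent identifier of
#'   instances of its class.
#' @param inlined For class-valued ranges, whether the value is an embedded
#'   instance (recursively extracted) rather than a grounded reference.
#' @export
attribute_definition <- function(name, range = "string", prompt = NULL,
                                 multivalued = FALSE, identifier = FALSE,
                                 inlined = FALSE) {
  structure(
    list(
      name = name,
      prompt = prompt,
      multivalued = isTRUE(multivalued),
      identifier = isTRUE(identifier),
      inlined = isTRUE(inlined),
      range = range
    ),
    class = "pkb_attribute"
  )
}

#' @rdname schema_definition
#' @param extensional Explicit character vector of member CURIEs, or `NULL`.
#' @param intensional A list with elements `source`, `include` (root CURIEs
#'   whose reflexive-transitive descendants are included) and `exclude`
#'   (roots whose descendants are removed), or `NULL`. Exactly one of
#'   `extensional`/`intensional` must be given.
#' @export
value_set_spec <- function(name, extensional = NULL, intensional = NULL) {
  if (is.null(extensional) == is.null(intensional)) {
    pkb_stop("pkb_malformed_document",
             sprintf("value set '%s': exactly one of extensional/intensional must be set", name))
  }
  if (!is.null(intensional)) {
    intensional$include <- as.character(intensional$include %||% character())
    intensional$exclude <- as.character(intensional$exclude %||% character())
  }
  structure(
    list(name = name, extensional = extensional, intensional = intensional),
    class = "pkb_value_set"
  )
}

PRIMITIVE_RANGES <- c("string", "number", "boolean")

# Load-time structural errors: unresolved ranges, dangling entry class,
# cyclic inlined ranges. Softer invariants are reported by validate_schema().
check_schema_structure <- function(schema) {
  class_names <- names(schema$classes)
  if (anyDuplicated(class_names)) {
    pkb_stop("pkb_malformed_document",
             paste0("duplicate class names: ",
                    paste(unique(class_names[duplicated(class_names)]), collapse = ", ")))
  }
  if (!schema$entry_class %in% class_names) {
    pkb_stop("pkb_unresolved_class",
             sprintf("entry class '%s' is not a declared class", schema$entry_class))
  }
  for (cls in schema$classes) {
    for (att in cls$attributes) {
      known <- att$range %in% PRIMITIVE_RANGES ||
        att$range %in% class_names ||
        att$range %in% names(schema$value_sets)
      if (!known) {
        pkb_stop("pkb_unresolved_range",
                 sprintf("unresolved range '%s' at %s.%s", att$range, cls$name, att$name))
      }
    }
    if (!is.null(cls$values_from) && !cls$values_from %in% names(schema$value_sets)) {
      pkb_stop("pkb_unresolved_range",
               sprintf("class '%s' references undeclared value set '%s'",
                       cls$name, cls$values_from))
    }
  }
  cycle <- find_inlined_cycle(schema)
  if (!is.null(cycle)) {
    pkb_stop("pkb_cycle_error",
             paste0("cycle of inlined class ranges: ", paste(cycle, collapse = " -> ")))
  }
  invisible(schema)
}

# Depth-first search over the directed graph whose edges are inlined
# class-valued ranges; recursion during extraction terminates only if this
# graph is acyclic.
find_inlined_cycle <- function(schema) {
  edges <- lapply(schema$classes, function(cls) {
    targets <- vapply(cls$attributes, function(a) {
      if (a$inlined && a$range %in% names(schema$classes)) a$range else NA_character_
    }, character(1L))
    unname(targets[!is.na(targets)])
  })
  state <- new.env(parent = emptyenv())
  for (cn in names(edges)) state[[cn]] <- 0L  # 0 unseen, 1 on stack, 2 done
  visit <- function(node, path) {
    if (state[[node]] == 1L) {
      return(c(path[which(path == node)[1L]:length(path)], node))
    }
    if (state[[node]] == 2L) return(NULL)
    state[[node]] <- 1L
    for (nxt in edges[[node]]) {
      cyc <- visit(nxt, c(path, node))
      if (!is.null(cyc)) return(cyc)
    }
    state[[node]] <- 2L
    NULL
  }
  for (cn in names(edges)) {
    cyc <- visit(cn, character())
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' Validate a loaded schema
#'
#' Checks the invariants that are not hard load-time errors and returns the
#' violations as data, not exceptions: upper-case identifier prefixes,
#' `inlined` only on class-valued ranges, at most one identifier attribute
#' per class, value sets implying named-entity status.
#'
#' @param schema A `pkb_schema`.
#' @return A data frame with columns `severity`, `path`, `message`; zero rows
#'   when all invariants hold.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "pkb_schema"))
  issues <- list()
  add <- function(severity, path, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, path = path, message = message,
      stringsAsFactors = FALSE
    )
  }
  for (cls in schema$classes) {
    bad_prefix <- cls$id_prefixes[cls$id_prefixes != toupper(cls$id_prefixes)]
    for (p in bad_prefix) {
      add("error", cls$name,
          sprintf("identifier prefix '%s' must be upper-case", p))
    }
    n_ident <- sum(vapply(cls$attributes, function(a) a$identifier, logical(1L)))
    if (n_ident > 1L) {
      add("error", cls$name, "more than one attribute marked as identifier")
    }
    if (!is.null(cls$values_from) && !cls$named_entity) {
      add("error", cls$name,
          "class has a value set but is not marked as a named entity")
    }
    for (att in cls$attributes) {
      if (att$inlined && !att$range %in% names(schema$classes)) {
        add("error", paste0(cls$name, ".", att$name),
            sprintf("inlined is only meaningful for class-valued ranges (range is '%s')", att$range))
      }
      if (anyDuplicated(names(cls$attributes))) {
        # reported once per class below
      }
    }
    dup <- unique(names(cls$attributes)[duplicated(names(cls$attributes))])
    for (d in dup) {
      add("error", paste0(cls$name, ".", d), "duplicate attribute name")
    }
  }
  for (vs in schema$value_sets) {
    if (is.null(vs$extensional) == is.null(vs$intensional)) {
      add("error", vs$name, "value set must be exactly one of extensional/intensional")
    }
  }
  if (length(issues) == 0L) {
    return(empty_df(severity = "character", path = "character", message = "character"))
  }
  do.call(rbind, issues)
}

#' Resolve the range of an attribute
#'
#' @param schema A `pkb_schema`.
#' @param attribute A `pkb_attribute` belonging to one of its classes.
#' @return A list with `kind` (one of `"primitive"`, `"class-inlined"`,
#'   `"class-reference"`, `"value-set"`) and `target` (the range name).
#' @export
resolve_range <- function(schema, attribute) {
  stopifnot(inherits(schema, "pkb_schema"), inherits(attribute, "pkb_attribute"))
  r <- attribute$range
  if (r %in% PRIMITIVE_RANGES) {
    return(list(kind = "primitive", target = r))
  }
  if (r %in% names(schema$classes)) {
    kind <- if (attribute$inlined) "class-inlined" else "class-reference"
    return(list(kind = kind, target = r))
  }
  if (r %in% names(schema$value_sets)) {
    return(list(kind = "value-set", target = r))
  }
  pkb_stop("pkb_unresolved_range",
           sprintf("unresolved range '%s' at attribute '%s'", r, attribute$name))
}

schema_class <- function(schema, class_name) {
  cls <- schema$classes[[class_name]]
  if (is.null(cls)) {
    pkb_stop("pkb_unresolved_class",
             sprintf("class '%s' is not declared in schema '%s'", class_name, schema$name))
  }
  cls
}

#' Serialize a schema back to the YAML dialect
#'
#' The serialization is canonical: loading its output reproduces a
#' structurally identical schema (round-trip property).
#'
#' @param schema A `pkb_schema`.
#' @return A single YAML string.
#' @export
schema_to_yaml <- function(schema) {
  stopifnot(inherits(schema, "pkb_schema"))
  doc <- list(
    name = schema$name,
    entry_class = schema$entry_class
  )
  if (length(schema$prefixes)) doc$prefixes <- as.list(schema$prefixes)
  if (length(schema$value_sets)) {
    doc$value_sets <- lapply(schema$value_sets, function(vs) {
      if (!is.null(vs$extensional)) {
        list(curies = as.list(vs$extensional))
      } else {
        out <- list(source = vs$intensional$source,
                    include = as.list(vs$intensional$include))
        if (length(vs$intensional$exclude)) {
          out$exclude <- as.list(vs$intensional$exclude)
        }
        out
      }
    })
  }
  doc$classes <- lapply(schema$classes, function(cls) {
    body <- list()
    if (cls$named_entity) body$named_entity <- TRUE
    if (length(cls$id_prefixes)) body$id_prefixes <- as.list(cls$id_prefixes)
    if (!is.null(cls$values_from)) body$values_from <- cls$values_from
    body$attributes <- lapply(cls$attributes, function(att) {
      ab <- list(range = att$range)
      if (!is.null(att$prompt)) ab$prompt <- att$prompt
      if (att$multivalued) ab$multivalued <- TRUE
      if (att$identifier) ab$identifier <- TRUE
      if (att$inlined) ab$inlined <- TRUE
      ab
    })
    body
  })
  yaml::as.yaml(doc)
}

#' @rdname schema_to_yaml
#' @param path File path to write the document to.
#' @export
write_schema <- function(schema, path) {
  writeLines(schema_to_yaml(schema), path, sep = "")
  invisible(path)
}

#' @export
print.pkb_schema <- function(x, ...) {
  cat(sprintf("<knowledge schema '%s'>\n", x$name))
  cat(sprintf("  entry class: %s\n", x$entry_class))
  for (cls in x$classes) {
    tags <- c(
      if (cls$named_entity) "named entity",
      if (length(cls$id_prefixes)) paste0("prefixes: ", paste(cls$id_prefixes, collapse = ",")),
      if (!is.null(cls$values_from)) paste0("values from ", cls$values_from)
    )
    cat(sprintf("  %s (%d attributes)%s\n", cls$name, length(cls$attributes),
                if (length(tags)) paste0(" [", paste(tags, collapse = "; "), "]") else ""))
  }
  invisible(x)
}
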