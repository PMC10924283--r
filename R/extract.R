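#' Parsing options for pseudo-YAML completions
#'
#' @param delimiter Token delimiter for multivalued attributes (default
#'   `";"`).
#' @param none_values Right-hand sides treated as empty, case-insensitively
#'   (typical model fillers for absent information).
#' @param strip_bullets Strip leading `-`/`*` list markers from lines.
#' @param strip_quotes Strip one layer of surrounding single or double
#'   quotes from values.
#' @return A `pkb_parse_options` list.
#' @export
parse_options <- function(delimiter = ";",
                          none_values = c("none", "n/a", "not mentioned",
                                          "not specified", "null"),
                          strip_bullets = TRUE,
                          strip_quotes = TRUE) {
  structure(
    list(delimiter = delimiter, none_values = tolower(none_values),
         strip_bullets = isTRUE(strip_bullets),
         strip_quotes = isTRUE(strip_quotes)),
    class = "pkb_parse_options"
  )
}

#' Heuristically parse a pseudo-YAML completion into an instance
#'
#' Model completions are near-YAML at best, so no strict parser is used.
#' The text is split into lines; each line is split at its first `":"`; the
#' left part is matched case-insensitively against the class's attribute
#' names after normalizing all whitespace to underscores; the right part is
#' parsed per the attribute's range and cardinality (see [parse_value()]).
#' Lines with no colon, an empty key, or an unknown key are recorded and
#' skipped, never fatal: the function is total on arbitrary byte strings.
#'
#' Duplicate attribute lines: single-valued attributes keep the first value
#' (later ones are recorded as conflicts); multivalued attributes
#' concatenate.
#'
#' @param raw Completion text (anything).
#' @param schema A `pkb_schema`.
#' @param class Target class name.
#' @param options A [parse_options()].
#' @return An ungrounded `pkb_instance`. Attributes `skipped` (data frame of
#'   skipped lines with reasons), `conflicts` and `warnings` carry parse
#'   provenance.
#' @export
parse_completion <- function(raw, schema, class, options = parse_options()) {
  cls <- schema_class(schema, class)
  inst <- instance_node(schema, class)
  skipped <- list()
  conflicts <- list()
  warnings <- character()

  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    raw <- paste(as.character(raw), collapse = "\n")
  }
  # totality on arbitrary byte strings: invalid encodings are replaced, not
  # propagated into the regex machinery
  if (!all(validUTF8(raw))) {
    raw <- iconv(raw, from = "UTF-8", to = "UTF-8", sub = "byte") %||% ""
    if (is.na(raw)) raw <- ""
  }
  # attribute-name lookup table: normalized -> declared name
  attr_names <- names(cls$attributes)
  norm_names <- normalize_attr_key(attr_names)

  lines <- strsplit(gsub("\r\n?", "\n", raw), "\n", fixed = TRUE)[[1L]]
  for (k in seq_along(lines)) {
    line <- lines[[k]]
    if (!nzchar(trimws(line))) next
    work <- line
    if (options$strip_bullets) work <- sub("^[[:space:]]*[-*]+[[:space:]]+", "", work)
    colon <- regexpr(":", work, fixed = TRUE)
    if (colon == -1L) {
      skipped[[length(skipped) + 1L]] <- list(line = k, text = line, reason = "no colon")
      next
    }
    key <- trimws(substr(work, 1L, colon - 1L))
    val <- trimws(substr(work, colon + 1L, nchar(work)))
    if (!nzchar(key)) {
      skipped[[length(skipped) + 1L]] <- list(line = k, text = line, reason = "empty key")
      next
    }
    hit <- match(normalize_attr_key(key), norm_names)
    if (is.na(hit)) {
      skipped[[length(skipped) + 1L]] <- list(line = k, text = line, reason = "unknown attribute")
      next
    }
    an <- attr_names[[hit]]
    att <- cls$attributes[[an]]
    parsed <- parse_value(val, att, schema, options)
    warnings <- c(warnings, attr(parsed, "warnings") %||% character())
    if (att$multivalued) {
      inst$values[[an]] <- c(inst$values[[an]], strip_attrs(parsed))
    } else {
      if (is.null(inst$values[[an]])) {
        inst$values[[an]] <- strip_attrs(parsed)
      } else if (!is.null(strip_attrs(parsed))) {
        conflicts[[length(conflicts) + 1L]] <-
          list(attribute = an, kept = "first", discarded = val)
      }
    }
  }

  attr(inst, "skipped") <- if (length(skipped)) {
    do.call(rbind, lapply(skipped, function(s) {
      data.frame(line = s$line, text = s$text, reason = s$reason,
                 stringsAsFactors = FALSE)
    }))
  } else {
    empty_df(line = "integer", text = "character", reason = "character")
  }
  attr(inst, "conflicts") <- conflicts
  attr(inst, "warnings") <- warnings
  inst
}

normalize_attr_key <- function(x) {
  tolower(gsub("[[:space:]]+", "_", trimws(x)))
}

strip_attrs <- function(x) {
  if (is.null(x)) return(NULL)
  attr(x, "warnings") <- NULL
  x
}

#' Parse one attribute value from a completion
#'
#' Applies the cardinality and range rules: a multivalued value is first
#' split on the delimiter (default `";"`) and each token trimmed; then, per
#' token, a primitive-ranged value is kept as-is (numbers are coerced when
#' the declared range is `number`; on coercion failure the string is kept
#' with a warning record); a class-reference or value-set range marks the
#' token as a mention to be grounded; an inlined class range marks the token
#' for recursive extraction, which proceeds until a non-inlined class is
#' reached.
#'
#' @param value_text Right-hand side text of an attribute line.
#' @param attribute A `pkb_attribute`.
#' @param schema A `pkb_schema`.
#' @param options A [parse_options()].
#' @return A single value, `NULL`, or (for multivalued attributes) a list of
#'   values; parse warnings are attached as an attribute.
#' @export
parse_value <- function(value_text, attribute, schema, options = parse_options()) {
  rng <- resolve_range(schema, attribute)
  warnings <- character()
  one <- function(tok) {
    tok <- clean_token(tok, options)
    if (is.null(tok)) return(NULL)
    switch(rng$kind,
      primitive = {
        if (rng$target == "number") {
          num <- suppressWarnings(as.numeric(tok))
          if (is.na(num)) {
            warnings <<- c(warnings, sprintf("cannot coerce '%s' to number; kept as string", tok))
            tok
          } else if (!is.na(suppressWarnings(as.integer(tok))) &&
                     as.integer(tok) == num) {
            as.integer(tok)
          } else {
            num
          }
        } else if (rng$target == "boolean") {
          b <- tolower(tok)
          if (b %in% c("true", "yes")) TRUE
          else if (b %in% c("false", "no")) FALSE
          else {
            warnings <<- c(warnings, sprintf("cannot coerce '%s' to boolean; kept as string", tok))
            tok
          }
        } else {
          tok
        }
      },
      `class-reference` = mention(tok, rng$target),
      `value-set` = mention(tok, rng$target),
      `class-inlined` = pending_instance(tok, rng$target)
    )
  }

  out <- if (attribute$multivalued) {
    toks <- strsplit(value_text, options$delimiter, fixed = TRUE)[[1L]]
    vals <- lapply(toks, one)
    vals[!vapply(vals, is.null, logical(1L))]
  } else {
    one(value_text)
  }
  if (length(warnings)) attr(out, "warnings") <- warnings
  out
}

clean_token <- function(tok, options) {
  tok <- trimws(tok)
  if (options$strip_quotes) {
    tok <- sub('^"(.*)"$', "\\1", tok)
    tok <- sub("^'(.*)'$", "\\1", tok)
    tok <- trimws(tok)
  }
  if (!nzchar(tok) || tolower(tok) %in% options$none_values) return(NULL)
  tok
}

#' Extract a schema instance from text
#'
#' The full pipeline for one text: generate the prompt for the target class,
#' complete it against the configured backend, heuristically parse the
#' completion, recurse over inlined class-valued attributes (each recursion
#' generates and completes a new prompt on the nested fragment), and ground
#' all leaf named-entity mentions against the supplied grounder. With
#' `chunk = TRUE` the document is first split by [chunk_text()], each chunk
#' extracted independently, and the per-chunk trees merged with
#' [merge_chunk_results()] before grounding.
#'
#' Recursion depth is bounded by the schema's inlined-range depth, which is
#' finite because cyclic inlined ranges are rejected at schema load time.
#'
#' @param schema A `pkb_schema`.
#' @param class Target class name; defaults to the schema's entry class.
#' @param text Input text.
#' @param config A [completion_config()].
#' @param grounder A [grounder()] or `NULL` (mentions then become
#'   placeholders).
#' @param chunk Chunk the document before extraction?
#' @param window,overlap Chunking parameters, see [chunk_text()].
#' @param style,wrap Prompt options, see [generate_prompt()].
#' @param options A [parse_options()].
#' @return A `pkb_result`: list with `instance` (the grounded tree),
#'   `records` (all completion records, in call order), `chunks` (chunk
#'   offsets or `NULL`), `unresolved` (data frame of spans that became
#'   placeholders), `skipped`, `conflicts`, `warnings`, `schema_name`,
#'   `class`.
#' @export
extract_instance <- function(schema, class = schema$entry_class, text,
                             config = completion_config(), grounder = NULL,
                             chunk = FALSE, window = 2500L, overlap = 250L,
                             style = "split", wrap = TRUE,
                             options = parse_options()) {
  stopifnot(inherits(schema, "pkb_schema"))
  schema_class(schema, class)

  state <- new.env(parent = emptyenv())
  state$records <- list()
  state$skipped <- list()
  state$conflicts <- list()
  state$warnings <- character()

  chunks <- NULL
  if (isTRUE(chunk)) {
    chunks <- chunk_text(text, window = window, overlap = overlap)
    parts <- lapply(chunks$text, function(piece) {
      extract_recursive(schema, class, piece, config, style, wrap, options, state)
    })
    inst <- merge_chunk_results(parts, schema, class)
    state$conflicts <- c(state$conflicts, attr(inst, "conflicts") %||% list())
  } else {
    inst <- extract_recursive(schema, class, text, config, style, wrap, options, state)
  }

  ground_state <- new.env(parent = emptyenv())
  ground_state$unresolved <- list()
  ground_state$labels <- character()
  inst <- ground_tree(inst, schema, grounder, ground_state, path = class)

  unresolved <- if (length(ground_state$unresolved)) {
    do.call(rbind, ground_state$unresolved)
  } else {
    empty_df(span = "character", path = "character", class = "character")
  }

  structure(
    list(
      instance = inst,
      records = state$records,
      chunks = chunks,
      unresolved = unresolved,
      skipped = if (length(state$skipped)) do.call(rbind, state$skipped) else
        empty_df(line = "integer", text = "character", reason = "character"),
      conflicts = state$conflicts,
      warnings = state$warnings,
      schema_name = schema$name,
      class = class
    ),
    class = "pkb_result"
  )
}

extract_recursive <- function(schema, class, text, config, style, wrap,
                              options, state) {
  if (!nzchar(trimws(text))) {
    return(instance_node(schema, class))
  }
  prompt <- generate_prompt(schema, class, text, style = style, wrap = wrap)
  rec <- complete(prompt, config)
  state$records[[length(state$records) + 1L]] <- rec
  inst <- parse_completion(rec$raw, schema, class, options)
  sk <- attr(inst, "skipped")
  if (nrow(sk)) state$skipped[[length(state$skipped) + 1L]] <- sk
  state$conflicts <- c(state$conflicts, attr(inst, "conflicts"))
  state$warnings <- c(state$warnings, attr(inst, "warnings"))

  # Recurse over pending inlined values.
  recurse_value <- function(v) {
    if (inherits(v, "pkb_pending")) {
      extract_recursive(schema, v$target, v$text, config, style, wrap, options, state)
    } else {
      v
    }
  }
  for (an in names(inst$values)) {
    v <- inst$values[[an]]
    if (is_empty_value(v)) next
    inst$values[[an]] <- if (is.list(v) && !is.object(v)) {
      lapply(v, recurse_value)
    } else {
      recurse_value(v)
    }
  }
  attr(inst, "skipped") <- NULL
  attr(inst, "conflicts") <- NULL
  attr(inst, "warnings") <- NULL
  inst
}

# Replace every mention in the tree by a grounded reference or a
# placeholder; placeholder labels are unique within one extraction result.
ground_tree <- function(inst, schema, grounder, state, path) {
  ground_value <- function(v, an) {
    if (inherits(v, "pkb_instance")) {
      return(ground_tree(v, schema, grounder, state, paste0(path, ".", an)))
    }
    if (inherits(v, "pkb_pending")) {
      # unrecursed pending (no backend for nested call): treat as mention
      v <- mention(v$text, v$target)
    }
    if (!inherits(v, "pkb_mention")) return(v)
    g <- NULL
    target_class <- schema$classes[[v$target]]
    constraint <- if (!is.null(target_class)) {
      target_class
    } else {
      # value-set range: anonymous named-entity constraint over the set
      class_definition(v$target, values_from = v$target, named_entity = TRUE)
    }
    if (!is.null(grounder) && constraint$named_entity) {
      g <- ground_span(v$span, constraint, grounder, schema = schema)
    }
    if (is.null(g) || inherits(g, "pkb_placeholder")) {
      lbl <- unique_label(camel_label(v$span), state)
      state$unresolved[[length(state$unresolved) + 1L]] <- data.frame(
        span = v$span, path = paste0(path, ".", an), class = v$target,
        stringsAsFactors = FALSE
      )
      return(placeholder(lbl, v$span))
    }
    g
  }
  for (an in names(inst$values)) {
    v <- inst$values[[an]]
    if (is_empty_value(v)) next
    inst$values[[an]] <- if (is.list(v) && !is.object(v)) {
      lapply(v, ground_value, an = an)
    } else {
      ground_value(v, an)
    }
  }
  inst
}

unique_label <- function(base, state) {
  if (!base %in% state$labels) {
    state$labels <- c(state$labels, base)
    return(base)
  }
  k <- 2L
  while (paste0(base, k) %in% state$labels) k <- k + 1L
  lbl <- paste0(base, k)
  state$labels <- c(state$labels, lbl)
  lbl
}

#' Merge per-chunk extraction results
#'
#' Combines instances of the same class extracted from overlapping document
#' chunks: multivalued attributes take the union of values in first-seen
#' order with duplicates removed by structural value equality; single-valued
#' attributes keep the first non-empty value, with later disagreeing values
#' recorded as conflicts (attached as the `conflicts` attribute).
#'
#' @param results List of `pkb_instance` objects of the same class.
#' @param schema A `pkb_schema`.
#' @param class The common class name.
#' @return A merged `pkb_instance`.
#' @export
merge_chunk_results <- function(results, schema, class) {
  cls <- schema_class(schema, class)
  for (r in results) {
    if (!inherits(r, "pkb_instance") || !identical(r$class, class)) {
      pkb_stop("pkb_invalid_merge",
               sprintf("all chunk results must instantiate class '%s'", class))
    }
  }
  merged <- instance_node(schema, class)
  conflicts <- list()
  for (an in names(cls$attributes)) {
    att <- cls$attributes[[an]]
    if (att$multivalued) {
      seen <- character()
      acc <- list()
      for (r in results) {
        for (v in r$values[[an]]) {
          key <- value_key(v)
          if (!key %in% seen) {
            seen <- c(seen, key)
            acc[[length(acc) + 1L]] <- v
          }
        }
      }
      merged$values[[an]] <- acc
    } else {
      for (r in results) {
        v <- r$values[[an]]
        if (is_empty_value(v)) next
        if (is.null(merged$values[[an]])) {
          merged$values[[an]] <- v
        } else if (value_key(v) != value_key(merged$values[[an]])) {
          conflicts[[length(conflicts) + 1L]] <-
            list(attribute = an, kept = value_key(merged$values[[an]]),
                 discarded = value_key(v))
        }
      }
    }
  }
  attr(merged, "conflicts") <- conflicts
  merged
}

value_key <- function(v) {
  paste(deparse(value_plain(v)), collapse = "")
}

#' @export
print.pkb_result <- function(x, ...) {
  cat(sprintf("<extraction result: %s / %s; %d completion(s), %d unresolved span(s)>\n",
              x$schema_name, x$class, length(x$records), nrow(x$unresolved)))
  print(x$instance)
  invisible(x)
}
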