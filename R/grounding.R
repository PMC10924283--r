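#' Normalize an entity label for lexical matching
#'
#' The matching policy used on both lexicon entries and query spans: Unicode
#' NFKC normalization, case folding, whitespace collapse, and terminal
#' punctuation stripping. Internal punctuation is preserved.
#'
#' @param x Character vector of labels.
#' @return Normalized labels.
#' @export
normalize_label <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  sub("[.,;:!?]+$", "", x)
}

#' Build a lexicon from a term table
#'
#' A lexicon maps labels and synonyms to CURIEs and is the offline stand-in
#' for ontology annotation services. Input is a tab-separated file (or data
#' frame) with columns `curie`, `label` and optional `is_synonym` (0/1) and
#' `priority` (smaller = preferred); `#`-prefixed lines are comments. Labels
#' are normalized with [normalize_label()]; duplicate (normalized label,
#' CURIE) pairs are collapsed keeping the best (smallest) priority. Rows with
#' malformed CURIEs (the prefix must be upper-case) are rejected with a
#' warning.
#'
#' @param x File path or data frame.
#' @param name Optional lexicon name (defaults to the file name).
#' @param default_priority Priority assigned to rows lacking one.
#' @return A `pkb_lexicon` with an `entries` data frame (`curie`, `prefix`,
#'   `label`, `norm_label`, `is_preferred`, `priority`).
#' @export
build_lexicon <- function(x, name = NULL, default_priority = 1L) {
  if (is.character(x)) {
    name <- name %||% basename(x)
    df <- utils::read.delim(x, header = TRUE, sep = "\t", quote = "",
                            comment.char = "#", stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    name <- name %||% "lexicon"
  }
  if (nrow(df) == 0L) {
    return(structure(
      list(name = name,
           entries = empty_df(curie = "character", prefix = "character",
                              label = "character", norm_label = "character",
                              is_preferred = "logical", priority = "integer")),
      class = "pkb_lexicon"
    ))
  }
  if (!all(c("curie", "label") %in% names(df))) {
    pkb_stop("pkb_invalid_input", "lexicon table requires 'curie' and 'label' columns")
  }
  df$curie <- trimws(as.character(df$curie))
  df$label <- as.character(df$label)
  bad <- !is_curie(df$curie)
  if (any(bad)) {
    pkb_warn("pkb_malformed_curie",
             sprintf("rejected %d lexicon row(s) with malformed CURIEs (e.g. '%s')",
                     sum(bad), df$curie[bad][1L]))
    df <- df[!bad, , drop = FALSE]
  }
  is_syn <- if ("is_synonym" %in% names(df)) as.integer(df$is_synonym) == 1L else
    rep(FALSE, nrow(df))
  prio <- if ("priority" %in% names(df)) {
    p <- suppressWarnings(as.integer(df$priority))
    ifelse(is.na(p), as.integer(default_priority), p)
  } else {
    rep(as.integer(default_priority), nrow(df))
  }
  entries <- data.frame(
    curie = df$curie,
    prefix = curie_prefix(df$curie),
    label = df$label,
    norm_label = normalize_label(df$label),
    is_preferred = !is_syn,
    priority = prio,
    stringsAsFactors = FALSE
  )
  # collapse duplicate (normalized label, curie) pairs, keeping best priority,
  # then restore document order
  ord <- seq_len(nrow(entries))
  entries <- entries[order(entries$priority, ord), , drop = FALSE]
  keep <- !duplicated(entries[, c("norm_label", "curie")])
  entries <- entries[keep, , drop = FALSE]
  entries <- entries[order(as.integer(rownames(entries))), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(name = name, entries = entries), class = "pkb_lexicon")
}

lexicon_lookup <- function(lexicon, span) {
  norm <- normalize_label(span)
  hits <- lexicon$entries[lexicon$entries$norm_label == norm, , drop = FALSE]
  if (nrow(hits)) hits$exact <- hits$label == trimws(span)
  hits
}

#' Bundle lexicons, identifier mappings and ontology edges for grounding
#'
#' @param lexicons A `pkb_lexicon` or list of them; order matters for
#'   candidate ranking.
#' @param mapping Optional identifier mapping table: data frame or TSV path
#'   with columns `from`, `to` (single-hop CURIE pairs, e.g. CHEBI to MeSH).
#' @param edges Optional ontology edge table for intensional value sets:
#'   data frame or TSV path with columns `child`, `parent`.
#' @return A `pkb_grounder`.
#' @export
grounder <- function(lexicons, mapping = NULL, edges = NULL) {
  if (inherits(lexicons, "pkb_lexicon")) lexicons <- list(lexicons)
  stopifnot(all(vapply(lexicons, inherits, logical(1L), "pkb_lexicon")))
  read_tsv <- function(x) {
    if (is.character(x)) {
      utils::read.delim(x, header = TRUE, sep = "\t", quote = "",
                        comment.char = "#", stringsAsFactors = FALSE)
    } else {
      x
    }
  }
  if (!is.null(mapping)) mapping <- read_tsv(mapping)
  if (!is.null(edges)) edges <- read_tsv(edges)
  structure(
    list(lexicons = lexicons, mapping = mapping, edges = edges,
         cache = new.env(parent = emptyenv())),
    class = "pkb_grounder"
  )
}

#' Ground a text span to a vocabulary identifier
#'
#' Looks the span up in every lexicon (normalized whole-span matching),
#' normalizes candidate identifiers through the mapping table when the
#' class's prefix constraints require it, then applies the class's
#' constraints: if identifier prefixes are declared, the candidate's prefix
#' must be among them; if a value set applies, the candidate CURIE must be a
#' member (both checks apply when both are present). Among survivors the
#' winner is chosen by a total tie-break: exact (verbatim) label match
#' first, then lexicon order, then entry priority, then lexicographically
#' smallest CURIE — so grounding is deterministic for a fixed lexicon order.
#'
#' When the whole span fails, a longest-prefix fallback is attempted before
#' giving up: first dropping a trailing parenthetical, then trailing tokens
#' one at a time. Fallback matches are reported with `kind = "normalized"`
#' and the truncated `matched_span`; failure to ground yields a
#' [placeholder()], never an error.
#'
#' @param span Text span naming an entity.
#' @param class_def A `pkb_class` with `named_entity = TRUE` (carries the
#'   `id_prefixes` and `values_from` constraints).
#' @param grounder A [grounder()].
#' @param schema Optional `pkb_schema`, required to resolve a `values_from`
#'   value set.
#' @return A `pkb_grounded` or a `pkb_placeholder`.
#' @export
ground_span <- function(span, class_def, grounder, schema = NULL) {
  stopifnot(inherits(grounder, "pkb_grounder"))
  if (!isTRUE(class_def$named_entity)) {
    pkb_stop("pkb_invalid_input",
             sprintf("class '%s' is not a named-entity class", class_def$name))
  }
  id_spaces <- class_def$id_prefixes %||% character()
  vset <- NULL
  if (!is.null(class_def$values_from)) {
    vset <- cached_value_set(class_def$values_from, schema, grounder)
  }

  for (attempt in fallback_spans(span)) {
    cands <- gather_candidates(attempt, grounder)
    if (nrow(cands) == 0L) next
    cands <- constrain_candidates(cands, id_spaces, vset, grounder$mapping)
    if (nrow(cands) == 0L) next
    cands <- cands[order(!cands$exact, cands$lex, cands$priority, cands$curie), ,
                   drop = FALSE]
    best <- cands[1L, ]
    kind <- if (best$exact && identical(attempt, trimws(span))) "exact" else "normalized"
    g <- grounded_ref(best$curie, best$label, span = span, kind = kind)
    g$matched_span <- attempt
    return(g)
  }
  placeholder(camel_label(span), span)
}

fallback_spans <- function(span) {
  out <- trimws(span)
  depar <- trimws(sub("[[:space:]]*\\([^()]*\\)[[:space:]]*$", "", out))
  if (nzchar(depar) && !identical(depar, out)) out <- c(out, depar)
  cur <- out[length(out)]
  repeat {
    nxt <- trimws(sub("[[:space:]]+[^[:space:]]+$", "", cur))
    if (identical(nxt, cur) || !nzchar(nxt)) break
    out <- c(out, nxt)
    cur <- nxt
  }
  unique(out)
}

gather_candidates <- function(attempt, grounder) {
  rows <- list()
  for (j in seq_along(grounder$lexicons)) {
    hits <- lexicon_lookup(grounder$lexicons[[j]], attempt)
    if (nrow(hits)) {
      hits$lex <- j
      rows[[length(rows) + 1L]] <- hits
    }
  }
  if (length(rows) == 0L) {
    return(empty_df(curie = "character", prefix = "character",
                    label = "character", norm_label = "character",
                    is_preferred = "logical", priority = "integer",
                    exact = "logical", lex = "integer"))
  }
  do.call(rbind, rows)
}

constrain_candidates <- function(cands, id_spaces, vset, mapping) {
  if (length(id_spaces)) {
    keep <- logical(nrow(cands))
    for (i in seq_len(nrow(cands))) {
      if (cands$prefix[i] %in% id_spaces) {
        keep[i] <- TRUE
      } else {
        mapped <- normalize_identifier(cands$curie[i], id_spaces, mapping)
        if (!is.na(mapped)) {
          cands$curie[i] <- mapped
          cands$prefix[i] <- curie_prefix(mapped)
          keep[i] <- TRUE
        }
      }
    }
    cands <- cands[keep, , drop = FALSE]
  }
  if (!is.null(vset) && nrow(cands)) {
    cands <- cands[cands$curie %in% vset, , drop = FALSE]
  }
  cands
}

cached_value_set <- function(vs_name, schema, grounder) {
  hit <- grounder$cache[[vs_name]]
  if (!is.null(hit)) return(hit)
  if (is.null(schema) || is.null(schema$value_sets[[vs_name]])) {
    pkb_stop("pkb_unresolved_root",
             sprintf("value set '%s' cannot be resolved without its schema declaration", vs_name))
  }
  members <- resolve_value_set(schema$value_sets[[vs_name]], grounder$edges)
  grounder$cache[[vs_name]] <- members
  members
}

#' Normalize a CURIE into a target prefix
#'
#' Identity when the identifier's prefix is already allowed; otherwise a
#' single-hop lookup in the mapping table for a partner identifier whose
#' prefix is allowed; otherwise `NA_character_` (the no-mapping signal).
#' Mapping chains are deliberately not followed.
#'
#' @param curie A well-formed CURIE.
#' @param target_prefixes Character vector of allowed prefixes.
#' @param mapping Data frame with columns `from`, `to`, or `NULL`.
#' @return The normalized CURIE, or `NA_character_`.
#' @export
normalize_identifier <- function(curie, target_prefixes, mapping = NULL) {
  if (!is_string(curie) || !is_curie(curie)) {
    pkb_stop("pkb_invalid_identifier",
             sprintf("malformed CURIE: '%s'", paste(curie, collapse = " ")))
  }
  if (curie_prefix(curie) %in% target_prefixes) return(curie)
  if (!is.null(mapping) && nrow(mapping)) {
    to <- mapping$to[mapping$from == curie]
    to <- to[curie_prefix(to) %in% target_prefixes]
    if (length(to)) return(sort(to)[1L])
  }
  NA_character_
}

#' Resolve a value set to its member CURIEs
#'
#' Extensional sets are returned as declared. Intensional sets are resolved
#' against an ontology edge table (columns `child`, `parent`): the members
#' are all reflexive-transitive descendants of the included roots minus all
#' reflexive-transitive descendants of the excluded roots.
#'
#' @param spec A `pkb_value_set` (see [value_set_spec()]).
#' @param edges Data frame with columns `child`, `parent`; required for
#'   intensional sets.
#' @return Character vector of member CURIEs.
#' @export
resolve_value_set <- function(spec, edges = NULL) {
  stopifnot(inherits(spec, "pkb_value_set"))
  if (!is.null(spec$extensional)) {
    return(unique(spec$extensional))
  }
  intension <- spec$intensional
  if (is.null(edges) || !all(c("child", "parent") %in% names(edges))) {
    pkb_stop("pkb_unresolved_root",
             sprintf("value set '%s' is intensional but no ontology edges were supplied", spec$name))
  }
  nodes <- unique(c(edges$child, edges$parent))
  for (r in c(intension$include, intension$exclude)) {
    if (!r %in% nodes) {
      pkb_stop("pkb_unresolved_root",
               sprintf("value set '%s': root '%s' not present in the ontology graph", spec$name, r))
    }
  }
  included <- descendants_closure(intension$include, edges)
  excluded <- descendants_closure(intension$exclude, edges)
  setdiff(included, excluded)
}

# Reflexive-transitive descendants of a set of roots over child->parent
# edges, by breadth-first expansion to a fixed point.
descendants_closure <- function(roots, edges) {
  if (length(roots) == 0L) return(character())
  seen <- unique(roots)
  frontier <- seen
  while (length(frontier)) {
    kids <- unique(edges$child[edges$parent %in% frontier])
    frontier <- setdiff(kids, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' @export
print.pkb_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s': %d entries, %d vocabularies>\n",
              x$name, nrow(x$entries), length(unique(x$entries$prefix))))
  invisible(x)
}
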