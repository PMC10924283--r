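#' Filter extracted relation statements before scoring
#'
#' Mirrors the benchmark preprocessing for chemical-induces-disease (CID)
#' style triples: statements whose predicate qualifier is `"NOT"`
#' (case-insensitive) are discarded entirely — negated relations must not be
#' scored as assertions — and subject/object qualifiers are cleared on the
#' survivors, because the reference benchmark does not test for them. Order
#' is preserved and the operation is idempotent.
#'
#' @param triples Data frame of triple records with (any of) columns
#'   `subject`, `predicate`, `object`, `predicate_qualifier`,
#'   `subject_qualifier`, `object_qualifier`, `doc_id`.
#' @return The filtered data frame.
#' @export
filter_statements <- function(triples) {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  for (col in c("predicate_qualifier", "subject_qualifier", "object_qualifier")) {
    if (!col %in% names(triples)) triples[[col]] <- NA_character_
  }
  pq <- toupper(trimws(ifelse(is.na(triples$predicate_qualifier), "",
                              triples$predicate_qualifier)))
  out <- triples[pq != "NOT", , drop = FALSE]
  out$subject_qualifier <- rep(NA_character_, nrow(out))
  out$object_qualifier <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  out
}

#' Score predicted triples against a gold standard
#'
#' Set comparison on (subject, predicate, object) keys — per source document
#' when `per_document = TRUE` (the benchmark convention), corpus-wide
#' otherwise. Predicted triples are deduplicated before matching, so each
#' prediction is counted once. Both inputs are expected to be pre-filtered
#' (see [filter_statements()]).
#'
#' Degenerate denominators follow the explicit conventions: precision is 0
#' when nothing was predicted, recall is 0 when the gold set is empty, and
#' the F-score is 0 when precision + recall is 0.
#'
#' @param predicted,gold Data frames with columns `subject`, `predicate`,
#'   `object` and (if `per_document`) `doc_id`.
#' @param per_document Include the source document id in the match key?
#' @return A `pkb_score`: list with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @export
score_triples <- function(predicted, gold, per_document = TRUE) {
  key <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(character())
    parts <- list(df$subject, df$predicate, df$object)
    if (per_document) parts <- c(list(df$doc_id), parts)
    unique(do.call(paste, c(parts, sep = "\r")))
  }
  pk <- key(predicted)
  gk <- key(gold)
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- sum(!gk %in% pk)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f_score <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f_score = f_score),
    class = "pkb_score"
  )
}

#' @export
print.pkb_score <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F = %.4f  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f_score, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Grounding accuracy over a term list
#'
#' The single-entity grounding protocol: each (label, gold CURIE) pair is
#' grounded with [ground_span()] and counts as correct only when the label
#' was treated as one whole entity — the matched lexicon label equals the
#' input label after normalization, so truncated fallback matches count as
#' incorrect — and grounded to exactly the gold identifier.
#'
#' @param terms Data frame with columns `label` and `curie` (the gold
#'   identifier).
#' @param grounder A [grounder()].
#' @param class_def Optional `pkb_class` carrying constraints; defaults to
#'   an unconstrained named-entity class.
#' @param schema Optional schema for value-set resolution.
#' @return List with `accuracy` (fraction correct; `NA` for an empty term
#'   list) and `outcomes` (per-term data frame with the grounded CURIE,
#'   matched label, and the `span_unchanged`/`correct` flags).
#' @export
grounding_accuracy <- function(terms, grounder, class_def = NULL, schema = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (is.null(class_def)) {
    class_def <- class_definition("Term", named_entity = TRUE)
  }
  if (nrow(terms) == 0L) {
    return(list(
      accuracy = NA_real_,
      outcomes = empty_df(label = "character", gold = "character",
                          curie = "character", matched_label = "character",
                          grounded = "logical", span_unchanged = "logical",
                          correct = "logical")
    ))
  }
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    lbl <- terms$label[i]
    gold <- terms$curie[i]
    g <- ground_span(lbl, class_def, grounder, schema = schema)
    grounded <- inherits(g, "pkb_grounded")
    unchanged <- grounded &&
      identical(normalize_label(g$label), normalize_label(lbl))
    data.frame(
      label = lbl, gold = gold,
      curie = if (grounded) g$curie else NA_character_,
      matched_label = if (grounded) g$label else NA_character_,
      grounded = grounded,
      span_unchanged = unchanged,
      correct = grounded && unchanged && identical(g$curie, gold),
      stringsAsFactors = FALSE
    )
  })
  outcomes <- do.call(rbind, rows)
  list(accuracy = mean(outcomes$correct), outcomes = outcomes)
}

#' Collect CID-style triples from an extracted document instance
#'
#' Walks the `associations` attribute of a chemical-to-disease document
#' instance and returns one triple record per association. Ungrounded
#' subjects or objects (placeholders) yield `NA` identifiers; callers
#' typically drop those rows before scoring.
#'
#' @param x A `pkb_result` or `pkb_instance` of the chemical-to-disease
#'   document shape (see [ctd_schema()]).
#' @param doc_id Source document identifier recorded on every row.
#' @return A data frame of triple records.
#' @export
collect_triples <- function(x, doc_id) {
  inst <- if (inherits(x, "pkb_result")) x$instance else x
  assocs <- inst$values$associations %||% list()
  scalar_of <- function(v) {
    if (is.null(v)) return(NA_character_)
    if (inherits(v, "pkb_grounded")) return(v$curie)
    if (inherits(v, "pkb_placeholder")) return(NA_character_)
    as.character(v)
  }
  qual_of <- function(v) {
    if (is.null(v)) NA_character_ else as.character(v)
  }
  if (length(assocs) == 0L) {
    return(empty_df(doc_id = "character", subject = "character",
                    predicate = "character", object = "character",
                    predicate_qualifier = "character",
                    subject_qualifier = "character",
                    object_qualifier = "character"))
  }
  do.call(rbind, lapply(assocs, function(a) {
    data.frame(
      doc_id = doc_id,
      subject = scalar_of(a$values$subject),
      predicate = qual_of(a$values$predicate),
      object = scalar_of(a$values$object),
      predicate_qualifier = qual_of(a$values$predicate_qualifier),
      subject_qualifier = qual_of(a$values$subject_qualifier),
      object_qualifier = qual_of(a$values$object_qualifier),
      stringsAsFactors = FALSE
    )
  }))
}
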