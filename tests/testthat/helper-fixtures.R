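# Shared fixtures built in code.

# Schema document with a cycle of inlined ranges (A -> B -> A).
cyclic_schema_doc <- function() {
  paste(
    "name: cyclic",
    "classes:",
    "  A:",
    "    attributes:",
    "      b: {range: B, inlined: true}",
    "  B:",
    "    attributes:",
    "      a: {range: A, inlined: true}",
    sep = "\n"
  )
}

# The four extracted-relation example rows (chemical-induces-disease), plus
# helpers to append negated statements.
example_cid_rows <- function() {
  data.frame(
    doc_id = c("2160002", "2160002", "19154241", "10327032"),
    subject = c("MESH:D019806", "MESH:D020110", "MESH:D008094", "MESH:D005472"),
    predicate = "INDUCES",
    object = c("MESH:D014664", "MESH:D014664", "MESH:D006934", "MESH:D001927"),
    predicate_qualifier = NA_character_,
    subject_qualifier = c(NA, NA, "Chronic", NA),
    object_qualifier = c("Large and small coronary vessels",
                         "Large and small coronary vessels", NA, "Transient"),
    stringsAsFactors = FALSE
  )
}

# Random triple tables over a small id universe, for scoring properties.
random_triples <- function(n, universe = 12L, docs = 3L) {
  if (n == 0L) {
    return(example_cid_rows()[0, c("doc_id", "subject", "predicate", "object")])
  }
  data.frame(
    doc_id = paste0("d", sample.int(docs, n, replace = TRUE)),
    subject = sprintf("MESH:C%03d", sample.int(universe, n, replace = TRUE)),
    predicate = "INDUCES",
    object = sprintf("MESH:D%03d", sample.int(universe, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}

# Nested-loop set-comparison oracle for precision/recall/F.
brute_force_score <- function(predicted, gold, per_document = TRUE) {
  key_rows <- function(df) {
    if (nrow(df) == 0L) return(character())
    k <- paste(df$subject, df$predicate, df$object, sep = "|")
    if (per_document) k <- paste(df$doc_id, k, sep = "|")
    unique(k)
  }
  pk <- key_rows(predicted)
  gk <- key_rows(gold)
  tp <- 0L
  for (p in pk) for (g in gk) if (identical(p, g)) tp <- tp + 1L
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  P <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  R <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  list(tp = tp, fp = fp, fn = fn, precision = P, recall = R, f_score = f)
}

# Random DAG over EX: nodes; edges child -> parent with parents drawn from
# earlier nodes, so acyclicity holds by construction.
random_dag_edges <- function(n_nodes) {
  nodes <- sprintf("EX:%03d", seq_len(n_nodes))
  rows <- list()
  for (i in seq_len(n_nodes)[-1]) {
    n_par <- sample(1:min(2L, i - 1L), 1L)
    for (p in sample(seq_len(i - 1L), n_par)) {
      rows[[length(rows) + 1L]] <- data.frame(
        child = nodes[[i]], parent = nodes[[p]], stringsAsFactors = FALSE
      )
    }
  }
  unique(do.call(rbind, rows))
}

# Independent reachability oracle via igraph.
igraph_descendants <- function(roots, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     vertices = unique(c(edges$child, edges$parent)))
  out <- character()
  for (r in roots) {
    out <- union(out, names(igraph::subcomponent(g, r, mode = "in")))
  }
  out
}

# A tiny lexicon data frame for grounding tests.
toy_lexicon_df <- function() {
  data.frame(
    curie = c("FOODON:03301844", "WIKIDATA:Q10716334", "FOODON:9990003"),
    label = c("garlic powder", "garlic powder", "sea salt"),
    stringsAsFactors = FALSE
  )
}

# Count grounded leaves carrying a given label in an instance tree.
count_label_uses <- function(inst, label) {
  n <- 0L
  for (v in inst$values) {
    vals <- if (is.list(v) && !is.object(v)) v else list(v)
    for (el in vals) {
      if (inherits(el, "pkb_instance")) n <- n + count_label_uses(el, label)
      if (inherits(el, "pkb_grounded") && identical(el$label, label)) n <- n + 1L
    }
  }
  n
}
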