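test_that("statement filtering drops NOT-qualified records and clears entity qualifiers", {
  rows <- example_cid_rows()
  neg <- rows[1, ]
  neg$predicate_qualifier <- "NOT"
  neg2 <- rows[2, ]
  neg2$predicate_qualifier <- "not"   # case-insensitive
  mixed <- rbind(rows, neg, neg2)
  out <- filter_statements(mixed)
  expect_identical(nrow(out), nrow(rows))
  expect_identical(out$subject, rows$subject)          # order preserved
  expect_true(all(is.na(out$subject_qualifier)))
  expect_true(all(is.na(out$object_qualifier)))
  # the qualified vasodilation row survives with its qualifier cleared
  expect_true("MESH:D019806" %in% out$subject)
  # idempotence
  expect_identical(filter_statements(out), out)
  # empty input
  expect_identical(nrow(filter_statements(rows[0, ])), 0L)
})

test_that("triple scoring follows the set-comparison arithmetic", {
  gold <- random_triples(0)
  gold <- data.frame(
    doc_id = "d1", subject = sprintf("MESH:C%03d", 1:5), predicate = "INDUCES",
    object = sprintf("MESH:D%03d", 1:5), stringsAsFactors = FALSE
  )
  pred <- rbind(gold[1:2, ], data.frame(
    doc_id = "d1", subject = c("MESH:C900", "MESH:C901"), predicate = "INDUCES",
    object = c("MESH:D900", "MESH:D901"), stringsAsFactors = FALSE
  ))
  s <- score_triples(pred, gold)
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 0.4)
  expect_equal(s$f_score, 4 / 9)

  # identity scores perfectly; duplicates in predictions count once
  s2 <- score_triples(rbind(gold, gold), gold)
  expect_equal(s2$precision, 1)
  expect_equal(s2$recall, 1)
  expect_equal(s2$f_score, 1)

  # degenerate conventions
  s3 <- score_triples(gold[0, ], gold)
  expect_identical(c(s3$precision, s3$recall, s3$f_score), c(0, 0, 0))
})

test_that("scoring agrees with a nested-loop oracle and respects the F bound", {
  withr::local_seed(23)
  for (rep in 1:150) {
    pred <- random_triples(sample(0:12, 1))
    gold <- random_triples(sample(0:12, 1))
    per_doc <- sample(c(TRUE, FALSE), 1)
    got <- score_triples(pred, gold, per_document = per_doc)
    want <- brute_force_score(pred, gold, per_document = per_doc)
    expect_equal(got[c("tp", "fp", "fn")], want[c("tp", "fp", "fn")])
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f_score, want$f_score)
    # harmonic mean never exceeds the arithmetic mean
    expect_lte(got$f_score, (got$precision + got$recall) / 2 + 1e-12)
  }
})

test_that("grounding accuracy requires whole-span single-entity matches", {
  lex_df <- data.frame(
    curie = sprintf("EX:%03d", 1:20),
    label = sprintf("synthetic term %02d", 1:20),
    stringsAsFactors = FALSE
  )
  terms <- data.frame(label = lex_df$label, curie = lex_df$curie,
                      stringsAsFactors = FALSE)
  full <- grounding_accuracy(terms, grounder(build_lexicon(lex_df)))
  expect_equal(full$accuracy, 1.0)

  # deleting one label drops exactly that term
  ablated <- grounding_accuracy(terms, grounder(build_lexicon(lex_df[-7, ])))
  expect_equal(ablated$accuracy, 19 / 20)
  expect_false(ablated$outcomes$correct[7])
  expect_true(all(ablated$outcomes$correct[-7]))

  # a truncated-span match is scored incorrect even when the id is right
  trunc_lex <- build_lexicon(data.frame(
    curie = "EX:900", label = "uv-induced skin damage", stringsAsFactors = FALSE
  ))
  trunc <- grounding_accuracy(
    data.frame(label = "uv-induced skin damage susceptibility", curie = "EX:900"),
    grounder(trunc_lex)
  )
  expect_identical(trunc$outcomes$curie, "EX:900")      # it did ground...
  expect_false(trunc$outcomes$span_unchanged)           # ...but not whole-span
  expect_equal(trunc$accuracy, 0)

  # empty term list: accuracy undefined, not 1.0
  expect_true(is.na(grounding_accuracy(terms[0, ], grounder(build_lexicon(lex_df)))$accuracy))
})

test_that("fixture corpora are deterministic under seed and leave the RNG alone", {
  a <- make_fixture_corpus(seed = 21, n_documents = 5, schema = "ctd")
  b <- make_fixture_corpus(seed = 21, n_documents = 5, schema = "ctd")
  expect_identical(a$completions, b$completions)
  expect_identical(a$documents, b$documents)
  expect_true(all(vapply(names(a$instances), function(id) {
    instance_identical(a$instances[[id]], b$instances[[id]])
  }, logical(1))))

  set.seed(77)
  before <- stats::runif(1)
  set.seed(77)
  invisible(make_fixture_corpus(seed = 1, n_documents = 2, schema = "recipe"))
  expect_identical(stats::runif(1), before)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  make_fixture_corpus(seed = 21, n_documents = 3, schema = "ctd", dir = dir1)
  make_fixture_corpus(seed = 21, n_documents = 3, schema = "ctd", dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})

test_that("render_completion inverts parse_completion on well-formed instances", {
  s <- recipe_schema()
  inst <- instance_node(s, "Ingredient")
  inst$values$food_item <- grounded_ref("FOODON:03301844", "garlic powder")
  q <- instance_node(s, "Quantity")
  q$values$value <- "2"
  q$values$unit <- grounded_ref("UO:9990002", "tablespoons")
  inst$values$amount <- q
  expect_identical(render_completion(inst, s),
                   "food_item: garlic powder\namount: 2 tablespoons")
  expect_identical(render_completion(instance_node(s, "Recipe"), s), "")

  # property: parse(render(x)) equals the ungrounded projection of x
  fx <- make_fixture_corpus(seed = 33, n_documents = 6, schema = "ctd")
  for (inst in fx$instances) {
    parsed <- parse_completion(render_completion(inst, fx$schema),
                               fx$schema, inst$class)
    skel <- instance_skeleton(parsed)
    # mentions carry the labels; pendings the flattened nested text
    expect_identical(names(skel), names(instance_skeleton(inst)))
  }
})

test_that("deleting a lexicon label turns exactly the affected leaves into placeholders", {
  fx <- make_fixture_corpus(seed = 13, n_documents = 6, schema = "recipe")
  drop_label <- "garlic powder"
  lex2 <- build_lexicon(fx$lexicon_df[fx$lexicon_df$label != drop_label, ])
  cfg <- completion_config("mock", completions = fx$completions)
  for (id in names(fx$documents)) {
    res <- extract_instance(fx$schema, text = fx$documents[[id]],
                            config = cfg, grounder = grounder(lex2))
    # every unresolved span is the deleted label, and nothing else fails
    expect_true(all(res$unresolved$span == drop_label))
    full <- extract_instance(fx$schema, text = fx$documents[[id]],
                             config = cfg, grounder = grounder(fx$lexicon))
    expect_identical(nrow(full$unresolved), 0L)
    expect_identical(nrow(res$unresolved),
                     count_label_uses(fx$instances[[id]], drop_label))
  }
})
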