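test_that("the worked payload parses to the ingredient's two fields", {
  s <- recipe_schema()
  inst <- parse_completion("food_item: garlic powder\namount: 2 tablespoons",
                           s, "Ingredient")
  expect_s3_class(inst$values$food_item, "pkb_mention")
  expect_identical(inst$values$food_item$span, "garlic powder")
  expect_identical(inst$values$food_item$target, "FoodItem")
  # inlined range: marked for recursive extraction, not yet recursed
  expect_s3_class(inst$values$amount, "pkb_pending")
  expect_identical(inst$values$amount$text, "2 tablespoons")
  expect_identical(inst$values$amount$target, "Quantity")
  expect_identical(nrow(attr(inst, "skipped")), 0L)
})

test_that("attribute matching is case-insensitive with whitespace normalized to underscores", {
  s <- recipe_schema()
  inst <- parse_completion("Food Item: sea salt", s, "Ingredient")
  expect_identical(inst$values$food_item$span, "sea salt")
  inst2 <- parse_completion("FOOD_ITEM: sea salt", s, "Ingredient")
  expect_identical(inst2$values$food_item$span, "sea salt")
})

test_that("unparseable lines are skipped with reasons, never fatal", {
  s <- recipe_schema()
  inst <- parse_completion("no colon line\n: empty key\nunknown_attr: v",
                           s, "Ingredient")
  expect_identical(unname(lengths(Filter(Negate(is.null), inst$values))), integer(0))
  sk <- attr(inst, "skipped")
  expect_identical(nrow(sk), 3L)
  expect_setequal(sk$reason, c("no colon", "empty key", "unknown attribute"))
})

test_that("parsing is total on arbitrary byte strings", {
  s <- recipe_schema()
  withr::local_seed(99)
  for (i in 1:300) {
    bytes <- as.raw(sample(1:255, sample(0:60, 1), replace = TRUE))
    expect_no_error(parse_completion(rawToChar(bytes), s, "Recipe"))
  }
})

test_that("multivalued values split on the delimiter and drop empty tokens", {
  s <- recipe_schema()
  att <- s$classes$Recipe$attributes$categories
  v <- parse_value("onion; garlic; salt", att, s)
  expect_identical(v, list("onion", "garlic", "salt"))
  expect_identical(parse_value("", att, s), list())
  expect_identical(parse_value(" ; ;", att, s), list())
})

test_that("filler values and near-YAML decoration are cleaned", {
  s <- recipe_schema()
  lab <- s$classes$Recipe$attributes$label
  expect_null(parse_value("None", lab, s))
  expect_null(parse_value("n/a", lab, s))
  expect_identical(parse_value("\"Quoted Label\"", lab, s), "Quoted Label")
  inst <- parse_completion("- label: bullet value", s, "Recipe")
  expect_identical(inst$values$label, "bullet value")
})

test_that("number coercion applies only to number ranges and degrades to string", {
  s <- schema_definition("nums", classes = list(
    A = class_definition("A", attributes = list(
      n = attribute_definition("n", range = "number"),
      b = attribute_definition("b", range = "boolean"),
      s = attribute_definition("s", range = "string")
    ))
  ))
  inst <- parse_completion("n: 42\nb: true\ns: 42", s, "A")
  expect_identical(inst$values$n, 42L)
  expect_true(inst$values$b)
  expect_identical(inst$values$s, "42")
  bad <- parse_completion("n: twelve", s, "A")
  expect_identical(bad$values$n, "twelve")
  expect_match(attr(bad, "warnings"), "coerce")
})

test_that("duplicate attribute lines: first wins for single-valued, concatenate for multivalued", {
  s <- recipe_schema()
  inst <- parse_completion("label: A\nlabel: B\ncategories: x\ncategories: y",
                           s, "Recipe")
  expect_identical(inst$values$label, "A")
  expect_identical(length(attr(inst, "conflicts")), 1L)
  expect_identical(inst$values$categories, list("x", "y"))
})

test_that("extraction recurses over inlined classes until a non-inlined class is reached", {
  s <- recipe_schema()
  cfg <- worked_example_config()
  grd <- grounder(recipe_lexicon())
  res <- extract_instance(s, "Ingredient", "garlic powder (2 tablespoons)",
                          config = cfg, grounder = grd)
  # exactly two completions: the ingredient prompt and the recursive quantity prompt
  expect_length(res$records, 2L)
  expect_identical(res$records[[2]]$prompt,
                   generate_prompt(s, "Quantity", "2 tablespoons"))
  inst <- res$instance
  expect_s3_class(inst$values$food_item, "pkb_grounded")
  expect_identical(inst$values$food_item$curie, "FOODON:03301844")
  expect_s3_class(inst$values$amount, "pkb_instance")
  expect_identical(inst$values$amount$values$value, "2")
  expect_identical(inst$values$amount$values$unit$curie, "UO:9990002")
  expect_identical(nrow(res$unresolved), 0L)
})

test_that("an empty completion yields an empty instance with no unresolved spans", {
  s <- recipe_schema()
  cfg <- completion_config("mock")  # no entries: fallback ""
  res <- extract_instance(s, "Ingredient", "anything", config = cfg,
                          grounder = grounder(recipe_lexicon()))
  expect_null(res$instance$values$food_item)
  expect_null(res$instance$values$amount)
  expect_identical(nrow(res$unresolved), 0L)
})

test_that("ungroundable mentions become placeholders listed as unresolved spans", {
  s <- recipe_schema()
  cfg <- completion_config("mock", completions = list())
  cfg$completions[[generate_prompt(s, "Ingredient", "frobnicant (1 pinch)")]] <-
    "food_item: frobnicant\namount: 1 pinch"
  cfg$completions[[generate_prompt(s, "Quantity", "1 pinch")]] <-
    "value: 1\nunit: pinch"
  res <- extract_instance(s, "Ingredient", "frobnicant (1 pinch)",
                          config = cfg, grounder = grounder(recipe_lexicon()))
  expect_s3_class(res$instance$values$food_item, "pkb_placeholder")
  expect_identical(res$instance$values$food_item$label, "Frobnicant")
  expect_setequal(res$unresolved$span, c("frobnicant", "pinch"))
})

test_that("round-trip: rendered completions re-extract to the source instances", {
  for (sch in c("recipe", "ctd")) {
    fx <- make_fixture_corpus(seed = 5, n_documents = 8, schema = sch)
    cfg <- completion_config("mock", completions = fx$completions)
    grd <- grounder(fx$lexicon)
    for (id in names(fx$documents)) {
      res <- extract_instance(fx$schema, text = fx$documents[[id]],
                              config = cfg, grounder = grd)
      expect_true(instance_identical(res$instance, fx$instances[[id]]))
    }
  }
})

test_that("merge_chunk_results unions multivalued values and keeps first single value", {
  s <- recipe_schema()
  a <- parse_completion("label: A\ncategories: x; y", s, "Recipe")
  b <- parse_completion("label: B\ncategories: y; z", s, "Recipe")
  m <- merge_chunk_results(list(a, b), s, "Recipe")
  expect_identical(m$values$label, "A")
  expect_identical(m$values$categories, list("x", "y", "z"))
  conf <- attr(m, "conflicts")
  expect_length(conf, 1L)
  expect_identical(conf[[1]]$attribute, "label")
  # idempotence and order-insensitivity up to ordering
  m2 <- merge_chunk_results(list(m, m), s, "Recipe")
  expect_true(instance_identical(m, m2))
  m3 <- merge_chunk_results(list(b, a), s, "Recipe")
  expect_setequal(unlist(m3$values$categories), c("x", "y", "z"))
  # class mismatch is an error
  q <- parse_completion("value: 2", s, "Quantity")
  expect_error(merge_chunk_results(list(a, q), s, "Recipe"),
               class = "pkb_invalid_merge")
})

test_that("chunked extraction merges per-chunk trees and dedupes the overlap", {
  fx_voc <- list(
    c(chem = "quorzanide", dis = "glistening fever"),
    c(chem = "betalaxene", dis = "cobalt rash")
  )
  s <- ctd_schema()
  fn <- function(prompt) {
    if (grepl("subject: <the chemical substance>", prompt, fixed = TRUE)) {
      frag <- sub(".*\nText:\n(.*)\n===$", "\\1", prompt)
      parts <- strsplit(frag, " INDUCES ", fixed = TRUE)[[1]]
      paste0("subject: ", parts[1], "\npredicate: INDUCES\nobject: ", parts[2])
    } else {
      hits <- character()
      for (v in fx_voc) {
        if (grepl(v[["chem"]], prompt, fixed = TRUE)) {
          hits <- c(hits, paste(v[["chem"]], "INDUCES", v[["dis"]]))
        }
      }
      if (length(hits)) paste0("associations: ", paste(hits, collapse = "; ")) else ""
    }
  }
  doc <- paste0(
    "Treatment with quorzanide was followed by glistening fever in all mice. ",
    strrep("Additional observation sentences pad this abstract considerably. ", 4),
    "Later, betalaxene exposure produced cobalt rash in the same cohort."
  )
  cfg <- completion_config("function", fn = fn)
  res <- extract_instance(s, text = doc, config = cfg,
                          grounder = grounder(ctd_lexicon()),
                          chunk = TRUE, window = 220, overlap = 80)
  expect_gt(nrow(res$chunks), 1L)
  tr <- collect_triples(res, "doc1")
  expect_identical(nrow(tr), 2L)  # duplicates across overlapping chunks collapse
  expect_setequal(tr$subject, c("MESH:D9900001", "MESH:D9900002"))
  expect_setequal(tr$object, c("MESH:D9910001", "MESH:D9910002"))
})
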