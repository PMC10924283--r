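test_that("lexicon labels are retrievable under normalization", {
  lex <- recipe_lexicon()
  hit <- promptkb:::lexicon_lookup(lex, "Garlic  Powder")
  expect_identical(hit$curie, "FOODON:03301844")
  expect_false(hit$exact)
  exact <- promptkb:::lexicon_lookup(lex, "garlic powder")
  expect_true(exact$exact)
})

test_that("lexicon building collapses duplicates by priority and rejects bad CURIEs", {
  df <- data.frame(
    curie = c("EX:1", "EX:1", "EX:2", "not a curie", "lower:3"),
    label = c("thing", "Thing", "thing", "junk", "junk2"),
    priority = c(2L, 1L, 5L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  expect_warning(lex <- build_lexicon(df), class = "pkb_malformed_curie")
  # (normalized label, curie) pairs are unique; best priority retained
  e <- lex$entries
  expect_identical(nrow(e), 2L)
  expect_identical(e$priority[e$curie == "EX:1"], 1L)
  # both curies remain candidates for the shared label
  expect_setequal(promptkb:::lexicon_lookup(lex, "thing")$curie, c("EX:1", "EX:2"))
  # empty input yields an empty lexicon
  expect_identical(nrow(build_lexicon(data.frame())$entries), 0L)
})

test_that("grounding honors identifier-prefix constraints", {
  grd <- grounder(recipe_lexicon())
  food <- recipe_schema()$classes$FoodItem
  g <- ground_span("garlic powder", food, grd)
  expect_s3_class(g, "pkb_grounded")
  expect_identical(g$curie, "FOODON:03301844")
  expect_identical(g$kind, "exact")
  expect_identical(g$prefix, "FOODON")

  mesh_only <- class_definition("FoodItem", id_prefixes = "MESH",
                                named_entity = TRUE)
  p <- ground_span("garlic powder", mesh_only, grd)
  expect_s3_class(p, "pkb_placeholder")
})

test_that("the candidate tie-break matches brute-force enumeration of the rule", {
  withr::local_seed(31)
  labels <- c("alpha thing", "beta thing", "gamma thing")
  for (rep in 1:40) {
    lex_a <- build_lexicon(data.frame(
      curie = sprintf("AAA:%d", sample(1:9, 3)),
      label = sample(labels, 3, replace = TRUE),
      priority = sample(1:3, 3, replace = TRUE)
    ), name = "a")
    lex_b <- build_lexicon(data.frame(
      curie = sprintf("BBB:%d", sample(1:9, 3)),
      label = sample(c(labels, toupper(labels)), 3, replace = TRUE),
      priority = sample(1:3, 3, replace = TRUE)
    ), name = "b")
    grd <- grounder(list(lex_a, lex_b))
    cls <- class_definition("T", named_entity = TRUE)
    span <- sample(labels, 1)
    g <- ground_span(span, cls, grd)

    # brute force: gather all candidates, rank by (exact, lexicon, priority, curie)
    cands <- do.call(rbind, lapply(seq_along(grd$lexicons), function(j) {
      e <- grd$lexicons[[j]]$entries
      e <- e[e$norm_label == normalize_label(span), , drop = FALSE]
      if (nrow(e)) cbind(e, lex = j, exact = e$label == span) else NULL
    }))
    if (is.null(cands) || nrow(cands) == 0) {
      expect_s3_class(g, "pkb_placeholder")
    } else {
      cands <- cands[order(!cands$exact, cands$lex, cands$priority, cands$curie), ]
      expect_identical(g$curie, cands$curie[[1]])
    }
  }
})

test_that("grounding falls back by truncating parentheticals then trailing tokens", {
  grd <- grounder(recipe_lexicon())
  food <- recipe_schema()$classes$FoodItem
  g <- ground_span("garlic powder (organic)", food, grd)
  expect_s3_class(g, "pkb_grounded")
  expect_identical(g$curie, "FOODON:03301844")
  expect_identical(g$kind, "normalized")   # span changed before matching
  expect_identical(g$span, "garlic powder (organic)")
  expect_identical(g$matched_span, "garlic powder")

  g2 <- ground_span("sea salt flakes extra", food, grd)
  expect_identical(g2$curie, "FOODON:9990003")
  expect_identical(g2$matched_span, "sea salt")
})

test_that("identifier normalization is identity, single-hop mapping, or a no-mapping signal", {
  mapping <- utils::read.delim(
    system.file("extdata", "chebi-mesh-mapping-synthetic.tsv", package = "promptkb"),
    sep = "\t", comment.char = "#", stringsAsFactors = FALSE
  )
  expect_identical(normalize_identifier("MESH:D008094", "MESH", mapping),
                   "MESH:D008094")
  expect_identical(normalize_identifier("CHEBI:9900001", "MESH", mapping),
                   "MESH:D008094")
  expect_identical(normalize_identifier("CHEBI:123", "MESH", mapping),
                   NA_character_)
  expect_error(normalize_identifier("not a curie", "MESH", mapping),
               class = "pkb_invalid_identifier")
})

test_that("a mapped candidate satisfies prefix constraints end to end", {
  chebi_lex <- build_lexicon(data.frame(
    curie = "CHEBI:9900001", label = "lithium", stringsAsFactors = FALSE
  ), name = "chebi")
  mapping <- system.file("extdata", "chebi-mesh-mapping-synthetic.tsv",
                         package = "promptkb")
  grd <- grounder(chebi_lex, mapping = mapping)
  cls <- class_definition("Chemical", id_prefixes = "MESH", named_entity = TRUE)
  g <- ground_span("lithium", cls, grd)
  expect_identical(g$curie, "MESH:D008094")
  expect_identical(g$prefix, "MESH")
})

test_that("value sets resolve by branch inclusion and exclusion on a toy tree", {
  edges <- data.frame(child = c("EX:X", "EX:Y", "EX:Z"),
                      parent = c("EX:R", "EX:R", "EX:X"),
                      stringsAsFactors = FALSE)
  inc_r <- value_set_spec("v", intensional = list(include = "EX:R", exclude = "EX:X"))
  expect_setequal(resolve_value_set(inc_r, edges), c("EX:R", "EX:Y"))
  inc_x <- value_set_spec("v", intensional = list(include = "EX:X"))
  expect_setequal(resolve_value_set(inc_x, edges), c("EX:X", "EX:Z"))
  ext <- value_set_spec("v", extensional = c("EX:A", "EX:B"))
  expect_setequal(resolve_value_set(ext), c("EX:A", "EX:B"))
  bad <- value_set_spec("v", intensional = list(include = "EX:NOPE"))
  expect_error(resolve_value_set(bad, edges), class = "pkb_unresolved_root")
})

test_that("value-set resolution agrees with an independent reachability oracle", {
  withr::local_seed(17)
  for (rep in 1:40) {
    edges <- random_dag_edges(sample(5:50, 1))
    nodes <- unique(c(edges$child, edges$parent))
    include <- sample(nodes, sample(1:2, 1))
    exclude <- if (stats::runif(1) < 0.5) sample(nodes, 1) else character()
    spec <- value_set_spec("v", intensional = list(include = include,
                                                   exclude = exclude))
    got <- resolve_value_set(spec, edges)
    want <- setdiff(igraph_descendants(include, edges),
                    igraph_descendants(exclude, edges))
    expect_setequal(got, want)
  }
})

test_that("value-set membership constrains grounding", {
  s <- ctd_schema()
  grd <- grounder(ctd_lexicon())
  dis <- s$classes$Disease
  g <- ground_span("Vasodilation", dis, grd, schema = s)
  expect_identical(g$curie, "MESH:D014664")
  # a chemical label cannot ground as a Disease: it fails the value set
  p <- ground_span("Cromakalim", dis, grd, schema = s)
  expect_s3_class(p, "pkb_placeholder")
})

test_that("grounded references never violate class constraints across random corpora", {
  for (seed in c(3, 4)) {
    fx <- make_fixture_corpus(seed = seed, n_documents = 6, schema = "ctd")
    cfg <- completion_config("mock", completions = fx$completions)
    grd <- grounder(fx$lexicon)
    sets <- list(
      Chemical = resolve_value_set(fx$schema$value_sets$ChemicalSet),
      Disease = resolve_value_set(fx$schema$value_sets$DiseaseSet)
    )
    check <- function(inst) {
      cls <- fx$schema$classes[[inst$class]]
      for (an in names(inst$values)) {
        v <- inst$values[[an]]
        if (promptkb:::is_empty_value(v)) next
        vals <- if (is.list(v) && !is.object(v)) v else list(v)
        target <- fx$schema$classes[[cls$attributes[[an]]$range]]
        for (el in vals) {
          if (inherits(el, "pkb_instance")) check(el)
          if (inherits(el, "pkb_grounded")) {
            expect_true(el$prefix %in% target$id_prefixes)
            if (!is.null(target$values_from)) {
              expect_true(el$curie %in% sets[[target$name]])
            }
          }
        }
      }
    }
    for (id in names(fx$documents)) {
      res <- extract_instance(fx$schema, text = fx$documents[[id]],
                              config = cfg, grounder = grd)
      check(res$instance)
    }
  }
})
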