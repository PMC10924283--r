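#' Packaged fixture schemas and lexicons
#'
#' `recipe_schema()` loads the packaged recipe schema (a top-level `Recipe`
#' composed of a label, description, categories, steps, and ingredients;
#' ingredients decompose into a referenced `FoodItem` and an inlined
#' `Quantity`). `ctd_schema()` builds the chemical-to-disease association
#' schema: a document holding multivalued inlined associations with subject
#' chemical, fixed predicate, object disease, and subject/object/predicate
#' qualifiers, with MeSH-constrained named entities restricted by explicit
#' value sets.
#'
#' `recipe_lexicon()` and `ctd_lexicon()` return the matching synthetic
#' lexicons. Except for groundings that are themselves well known
#' (`FOODON:03301844` for "garlic powder", and the handful of MeSH
#' chemical/disease identifiers used in the association examples), all
#' identifiers and labels in these lexicons are synthetic stand-ins for real
#' ontology annotator output.
#'
#' @return A `pkb_schema` / `pkb_lexicon`.
#' @export
recipe_schema <- function() {
  load_schema(system.file("extdata", "recipe-schema.yaml", package = "promptkb",
                          mustWork = TRUE))
}

#' @rdname recipe_schema
#' @export
recipe_lexicon <- function() {
  build_lexicon(system.file("extdata", "recipe-lexicon-synthetic.tsv",
                            package = "promptkb", mustWork = TRUE),
                name = "recipe-lexicon")
}

# Fixture vocabularies. Identifiers marked synthetic do not exist in any
# real vocabulary; the remainder are printed, well-known groundings.
recipe_vocab <- function() {
  list(
    foods = c(
      "garlic powder" = "FOODON:03301844",  # real grounding
      "chopped onion" = "FOODON:9990001",
      "olive oil" = "FOODON:9990002",
      "sea salt" = "FOODON:9990003",
      "black pepper" = "FOODON:9990004",
      "wheat flour" = "FOODON:9990005",
      "brown sugar" = "FOODON:9990006",
      "tomato paste" = "FOODON:9990007",
      "fresh basil" = "FOODON:9990008",
      "ground cumin" = "FOODON:9990009",
      "lemon juice" = "FOODON:9990010",
      "butter" = "FOODON:9990011"
    ),
    units = c(
      "tablespoons" = "UO:9990002",
      "teaspoons" = "UO:9990003",
      "cups" = "UO:9990004",
      "grams" = "UO:9990005",
      "milliliters" = "UO:9990006"
    ),
    actions = c("mix", "chop", "bake", "simmer", "whisk", "saute"),
    categories = c("weeknight dinner", "dessert", "side dish", "breakfast"),
    adjectives = c("hearty", "zesty", "rustic", "golden", "smoky", "silky")
  )
}

ctd_vocab <- function() {
  list(
    chemicals = c(
      "Cromakalim" = "MESH:D019806",
      "Pinacidil" = "MESH:D020110",
      "Lithium" = "MESH:D008094",
      "Fluorouracil" = "MESH:D005472",
      "quorzanide" = "MESH:D9900001",    # synthetic
      "betalaxene" = "MESH:D9900002",    # synthetic
      "movantrol" = "MESH:D9900003",     # synthetic
      "serpentafil" = "MESH:D9900004"    # synthetic
    ),
    diseases = c(
      "Vasodilation" = "MESH:D014664",
      "Hypercalcemia" = "MESH:D006934",
      "Brain Diseases" = "MESH:D001927",
      "glistening fever" = "MESH:D9910001",  # synthetic
      "cobalt rash" = "MESH:D9910002",       # synthetic
      "marbled anemia" = "MESH:D9910003",    # synthetic
      "vesper syndrome" = "MESH:D9910004",   # synthetic
      "tidal migraine" = "MESH:D9910005"     # synthetic
    ),
    subject_qualifiers = c("Chronic", "Acute"),
    object_qualifiers = c("Transient", "Severe")
  )
}

#' @rdname recipe_schema
#' @export
ctd_schema <- function() {
  voc <- ctd_vocab()
  schema_definition(
    name = "ctd",
    prefixes = c(
      MESH = "http://id.nlm.nih.gov/mesh/",
      CHEBI = "http://purl.obolibrary.org/obo/CHEBI_",
      ctd = "http://example.org/ctd/"
    ),
    value_sets = list(
      ChemicalSet = value_set_spec("ChemicalSet", extensional = unname(voc$chemicals)),
      DiseaseSet = value_set_spec("DiseaseSet", extensional = unname(voc$diseases))
    ),
    classes = list(
      ChemicalToDiseaseDocument = class_definition(
        "ChemicalToDiseaseDocument",
        attributes = list(
          associations = attribute_definition(
            "associations", range = "ChemicalToDiseaseAssociation",
            prompt = "chemical to disease relationships described in the text",
            multivalued = TRUE, inlined = TRUE
          )
        )
      ),
      ChemicalToDiseaseAssociation = class_definition(
        "ChemicalToDiseaseAssociation",
        attributes = list(
          subject = attribute_definition("subject", range = "Chemical",
                                         prompt = "the chemical substance"),
          predicate = attribute_definition("predicate", range = "string",
                                           prompt = "the relationship type"),
          predicate_qualifier = attribute_definition("predicate_qualifier"),
          subject_qualifier = attribute_definition("subject_qualifier"),
          object = attribute_definition("object", range = "Disease",
                                        prompt = "the disease or condition"),
          object_qualifier = attribute_definition("object_qualifier")
        )
      ),
      Chemical = class_definition("Chemical", id_prefixes = "MESH",
                                  values_from = "ChemicalSet"),
      Disease = class_definition("Disease", id_prefixes = "MESH",
                                 values_from = "DiseaseSet")
    ),
    entry_class = "ChemicalToDiseaseDocument"
  )
}

#' @rdname recipe_schema
#' @export
ctd_lexicon <- function() {
  voc <- ctd_vocab()
  build_lexicon(
    data.frame(
      curie = c(unname(voc$chemicals), unname(voc$diseases)),
      label = c(names(voc$chemicals), names(voc$diseases)),
      stringsAsFactors = FALSE
    ),
    name = "ctd-lexicon"
  )
}

#' Mock configuration reproducing the worked ingredient example
#'
#' A mock backend whose canned completions answer the prompts for the recipe
#' `Ingredient` class on `"garlic powder (2 tablespoons)"` and the recursive
#' `Quantity` prompt on `"2 tablespoons"`, so the full pipeline can be run
#' deterministically offline.
#'
#' @return A [completion_config()] with the `"mock"` backend.
#' @export
worked_example_config <- function() {
  s <- recipe_schema()
  comps <- list()
  comps[[generate_prompt(s, "Ingredient", "garlic powder (2 tablespoons)")]] <-
    "food_item: garlic powder\namount: 2 tablespoons"
  comps[[generate_prompt(s, "Quantity", "2 tablespoons")]] <-
    "value: 2\nunit: tablespoons"
  completion_config("mock", completions = comps)
}

#' Render an instance as the completion text a well-behaved model would emit
#'
#' The inverse of [parse_completion()] on well-formed output: one
#' `name: value` line per populated attribute, in schema order; multivalued
#' values joined with `"; "`; grounded values rendered as their labels;
#' nested inlined instances flattened to the text their recursive prompt
#' will receive — by default the child's rendered values joined by spaces,
#' overridable per class via `flatten`.
#'
#' @param instance A `pkb_instance`.
#' @param schema A `pkb_schema`.
#' @param flatten Named list (by class name) of `function(instance, schema)`
#'   overrides for the flat rendering of nested instances.
#' @return Completion text (empty string for an empty instance).
#' @export
render_completion <- function(instance, schema, flatten = list()) {
  stopifnot(inherits(instance, "pkb_instance"))
  cls <- schema_class(schema, instance$class)
  lines <- character()
  for (an in names(cls$attributes)) {
    v <- instance$values[[an]]
    if (is_empty_value(v)) next
    txt <- if (is.list(v) && !is.object(v)) {
      paste(vapply(v, completion_value_text, character(1L),
                   schema = schema, flatten = flatten), collapse = "; ")
    } else {
      completion_value_text(v, schema, flatten)
    }
    lines <- c(lines, paste0(an, ": ", txt))
  }
  paste(lines, collapse = "\n")
}

completion_value_text <- function(v, schema, flatten) {
  if (inherits(v, "pkb_instance")) return(flat_instance_text(v, schema, flatten))
  if (inherits(v, "pkb_grounded")) return(v$label)
  if (inherits(v, "pkb_placeholder")) return(v$span)
  if (inherits(v, "pkb_mention")) return(v$span)
  if (inherits(v, "pkb_pending")) return(v$text)
  as.character(v)
}

flat_instance_text <- function(inst, schema, flatten) {
  fn <- flatten[[inst$class]]
  if (is.function(fn)) return(fn(inst, schema))
  cls <- schema_class(schema, inst$class)
  parts <- character()
  for (an in names(cls$attributes)) {
    v <- inst$values[[an]]
    if (is_empty_value(v)) next
    parts <- c(parts, if (is.list(v) && !is.object(v)) {
      paste(vapply(v, completion_value_text, character(1L),
                   schema = schema, flatten = flatten), collapse = "; ")
    } else {
      completion_value_text(v, schema, flatten)
    })
  }
  paste(parts, collapse = " ")
}

#' Generate a deterministic synthetic fixture corpus
#'
#' Builds everything needed to run the pipeline offline against a known
#' truth: a fixture schema, random instance trees conforming to it, document
#' texts, a lexicon covering every named-entity label, canned completions
#' keyed by the exact prompts [generate_prompt()] will produce (including
#' all recursive prompts), and — for the chemical-to-disease schema — the
#' gold triple set derived from the instances. With a complete lexicon the
#' pipeline round-trip recovers every instance exactly, which is what the
#' round-trip tests assert.
#'
#' Output is fully deterministic under `seed` (the caller's RNG state is
#' saved and restored).
#'
#' @param seed Integer seed.
#' @param n_documents Number of instance trees / documents.
#' @param schema `"recipe"` or `"ctd"`.
#' @param dir Optional directory; when given, schema, lexicon, completions,
#'   documents and (ctd) gold triples are written there as plain-text files.
#' @return A list with `schema`, `instances`, `documents` (named character
#'   vector, names are document ids), `completions` (named list),
#'   `lexicon`, `lexicon_df`, `gold` (ctd only, else `NULL`), `vocab`.
#' @export
make_fixture_corpus <- function(seed, n_documents = 10L,
                                schema = c("recipe", "ctd"), dir = NULL) {
  schema_choice <- match.arg(schema)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  if (schema_choice == "recipe") {
    out <- make_recipe_corpus(n_documents)
  } else {
    out <- make_ctd_corpus(n_documents)
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_schema(out$schema, file.path(dir, "schema.yaml"))
    utils::write.table(out$lexicon_df, file.path(dir, "lexicon.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_completions(out$completions, file.path(dir, "completions.yaml"))
    utils::write.table(
      data.frame(doc_id = names(out$documents), text = unname(out$documents),
                 stringsAsFactors = FALSE),
      file.path(dir, "documents.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    if (!is.null(out$gold)) {
      utils::write.table(out$gold, file.path(dir, "gold.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
  }
  out
}

# Walk an instance tree, registering the canned completion for the prompt
# its (possibly recursive) extraction call will emit.
register_completions <- function(instance, text, schema, env) {
  key <- generate_prompt(schema, instance$class, text)
  val <- render_completion(instance, schema)
  if (!is.null(env$map[[key]]) && !identical(env$map[[key]], val)) {
    stop("fixture generator produced conflicting completions for one prompt")
  }
  env$map[[key]] <- val
  for (an in names(instance$values)) {
    v <- instance$values[[an]]
    if (is_empty_value(v)) next
    vals <- if (is.list(v) && !is.object(v)) v else list(v)
    for (el in vals) {
      if (inherits(el, "pkb_instance")) {
        register_completions(el, flat_instance_text(el, schema, list()), schema, env)
      }
    }
  }
}

make_recipe_corpus <- function(n_documents) {
  schema <- recipe_schema()
  voc <- recipe_vocab()
  env <- new.env(parent = emptyenv())
  env$map <- list()

  grounded_of <- function(label, curies) {
    grounded_ref(unname(curies[[label]]), label)
  }
  instances <- list()
  documents <- character()
  for (k in seq_len(n_documents)) {
    foods <- sample(names(voc$foods), sample(2:4, 1L))
    units <- sample(names(voc$units), length(foods), replace = TRUE)
    amounts <- as.character(sample(1:12, length(foods), replace = TRUE))
    inst <- instance_node(schema, "Recipe")
    inst$values$label <- paste(sample(voc$adjectives, 1L), foods[[1L]], "dish")
    inst$values$description <- paste0("A ", sample(voc$adjectives, 1L),
                                      " dish built around ", foods[[1L]], ".")
    inst$values$categories <- as.list(sample(voc$categories, sample(1:2, 1L)))
    inst$values$steps <- lapply(seq_len(sample(1:3, 1L)), function(j) {
      st <- instance_node(schema, "Step")
      st$values$action <- sample(voc$actions, 1L)
      st$values$input <- grounded_of(sample(foods, 1L), voc$foods)
      st
    })
    inst$values$ingredients <- lapply(seq_along(foods), function(j) {
      ing <- instance_node(schema, "Ingredient")
      ing$values$food_item <- grounded_of(foods[[j]], voc$foods)
      q <- instance_node(schema, "Quantity")
      q$values$value <- amounts[[j]]
      q$values$unit <- grounded_of(units[[j]], voc$units)
      ing$values$amount <- q
      ing
    })
    doc_id <- sprintf("recipe_%03d", k)
    doc <- paste0("Document ", doc_id, ". ", inst$values$label, ". ",
                  inst$values$description, " Uses ",
                  paste(foods, collapse = ", "), ".")
    register_completions(inst, doc, schema, env)
    instances[[doc_id]] <- inst
    documents[[doc_id]] <- doc
  }
  lexicon_df <- data.frame(
    curie = c(unname(voc$foods), unname(voc$units)),
    label = c(names(voc$foods), names(voc$units)),
    stringsAsFactors = FALSE
  )
  list(schema = schema, instances = instances, documents = documents,
       completions = env$map,
       lexicon = build_lexicon(lexicon_df, name = "recipe-lexicon"),
       lexicon_df = lexicon_df, gold = NULL, vocab = voc)
}

make_ctd_corpus <- function(n_documents) {
  schema <- ctd_schema()
  voc <- ctd_vocab()
  env <- new.env(parent = emptyenv())
  env$map <- list()

  instances <- list()
  documents <- character()
  for (k in seq_len(n_documents)) {
    n_assoc <- sample(1:3, 1L)
    chems <- sample(names(voc$chemicals), n_assoc)
    dis <- sample(names(voc$diseases), n_assoc)
    inst <- instance_node(schema, "ChemicalToDiseaseDocument")
    inst$values$associations <- lapply(seq_len(n_assoc), function(j) {
      a <- instance_node(schema, "ChemicalToDiseaseAssociation")
      a$values$subject <- grounded_ref(unname(voc$chemicals[[chems[[j]]]]),
                                       chems[[j]])
      a$values$predicate <- "INDUCES"
      if (stats::runif(1) < 0.2) a$values$predicate_qualifier <- "NOT"
      if (stats::runif(1) < 0.3) {
        a$values$subject_qualifier <- sample(voc$subject_qualifiers, 1L)
      }
      if (stats::runif(1) < 0.3) {
        a$values$object_qualifier <- sample(voc$object_qualifiers, 1L)
      }
      a$values$object <- grounded_ref(unname(voc$diseases[[dis[[j]]]]),
                                      dis[[j]])
      a
    })
    doc_id <- sprintf("%d", 2000000L + k)
    doc <- paste0("PMID ", doc_id, ". Abstract describing ",
                  paste(vapply(seq_len(n_assoc), function(j) {
                    paste(chems[[j]], "and", dis[[j]])
                  }, character(1L)), collapse = "; "), ".")
    register_completions(inst, doc, schema, env)
    instances[[doc_id]] <- inst
    documents[[doc_id]] <- doc
  }
  gold <- do.call(rbind, lapply(names(instances), function(doc_id) {
    collect_triples(instances[[doc_id]], doc_id)
  }))
  gold <- filter_statements(gold)
  lexicon_df <- data.frame(
    curie = c(unname(voc$chemicals), unname(voc$diseases)),
    label = c(names(voc$chemicals), names(voc$diseases)),
    stringsAsFactors = FALSE
  )
  list(schema = schema, instances = instances, documents = documents,
       completions = env$map,
       lexicon = build_lexicon(lexicon_df, name = "ctd-lexicon"),
       lexicon_df = lexicon_df, gold = gold, vocab = voc)
}
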