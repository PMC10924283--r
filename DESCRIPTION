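Package: promptkb
Title: Schema-Guided Zero-Shot Knowledge Extraction with Ontology Grounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Populates nested knowledge schemas from free text by generating
    structured prompts for a language-model completion backend, heuristically
    parsing the pseudo-YAML completions, recursing over inlined classes, and
    grounding extracted entity mentions against local lexicons under identifier
    prefix and value-set constraints. Includes a deterministic mock backend,
    synthetic fixture-corpus generators, grounding-accuracy and triple
    precision/recall/F evaluation utilities, and YAML/JSON/Turtle export of
    extracted instance trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
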