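# promptkb

Schema-guided, zero-shot knowledge extraction with ontology grounding, in R.

`promptkb` populates nested knowledge schemas from free text by prompting a
language-model completion backend with a structured template, heuristically
parsing the pseudo-YAML completion, recursing over nested (inlined) classes,
and grounding the extracted entity mentions against local vocabularies under
identifier-prefix and value-set constraints. It is aimed at knowledge-base
and ontology curators — in the life sciences and beyond — who want
machine-assisted population of *typed, nested* records (recipes, pathway
steps, chemical–disease associations) rather than flat entity lists, and who
need every leaf entity tied to a persistent identifier (CURIE) from a real
vocabulary instead of a free-text string or a hallucinated id.

## The method

A knowledge schema *S* is a set of classes; each class *c* carries an
ordered list of attributes. An attribute *a* has a name, an optional custom
prompt, a multivalued flag, and a range: a primitive (`string`, `number`,
`boolean`), another class (either *inlined*, i.e. embedded, or a
*reference* to a named entity), or a value set. Named-entity classes may
declare allowed identifier prefixes (e.g. `FOODON`, `MESH`; upper-case by
convention) and a value set — extensional (an explicit CURIE list) or
intensional (ontology branches to include/exclude).

Extraction of class *C* from text *T* proceeds in four steps:

1. **Prompt generation** — a deterministic template:
   `Instructions + one "name: <prompt>" line per attribute (schema order) +
   "Text:" + T + "==="`. Multivalued attributes announce
   "A semicolon-separated list of ...". Missing prompts are auto-generated
   from the attribute name (`food_item` → "the food item").
2. **Completion** — the prompt goes to a pluggable backend. A deterministic
   mock backend (canned completions keyed by exact prompt text) makes the
   whole pipeline testable offline; long documents can be pre-split by a
   sliding-window chunker whose per-chunk results are merged.
3. **Parsing and recursion** — the completion is near-YAML at best, so each
   line is split at its first `:`; keys are matched case-insensitively with
   whitespace normalized to underscores; unknown lines are recorded and
   skipped, never fatal. Multivalued values split on `;`. Values of inlined
   class ranges trigger a recursive extraction call on the fragment, until a
   non-inlined class is reached.
4. **Grounding** — leaf named-entity mentions are looked up (whole-span,
   normalized) in local lexicons, mapped across vocabularies where a
   single-hop identifier mapping exists, and validated against the class's
   prefix and value-set constraints. Spans that fail to ground become blank
   node placeholders (`_:ChoppedOnion`), never errors.

Results render as YAML (`FOODON:03301844 ## garlic powder`), canonical
JSON, or a Turtle instance graph. Evaluation utilities compute grounding
accuracy under a strict whole-span protocol, and precision / recall / F
over subject–predicate–object triples after discarding `NOT`-qualified
statements and entity qualifiers.

## Worked example

```r
library(promptkb)

schema <- recipe_schema()
cat(generate_prompt(schema, "Ingredient", "garlic powder (2 tablespoons)"))
#> Split the following piece of text into fields in the following format:
#> food_item: <the food item>
#> amount: <the quantity of the ingredient>
#> Text:
#> garlic powder (2 tablespoons)
#> ===

res <- extract_instance(
  schema, "Ingredient", "garlic powder (2 tablespoons)",
  config   = worked_example_config(),   # mock backend, canned completions
  grounder = grounder(recipe_lexicon())
)
print(res$instance)
#> Ingredient:
#>   food_item: FOODON:03301844 ## garlic powder
#>   amount:
#>     value: 2
#>     unit: UO:9990002 ## tablespoons
```

The backend answered `food_item: garlic powder` / `amount: 2 tablespoons`;
`amount` has an inlined `Quantity` range, so a second, recursive prompt was
completed for the fragment "2 tablespoons" (`res$records` holds both
completion records). "garlic powder" was grounded to its FOODON identifier
because the `FoodItem` class restricts identifiers to the `FOODON` prefix;
under a `MESH`-only constraint with no mapping it would have become a
placeholder. The unit identifier shown comes from the packaged *synthetic*
fixture lexicon.

A thin command-line front end with `extract`, `ground` and `score`
subcommands ships in `inst/cli/promptkb`.

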