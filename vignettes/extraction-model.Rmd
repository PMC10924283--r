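---
title: "Schema-guided zero-shot extraction: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema-guided zero-shot extraction: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptkb)
```

## The extraction model

`promptkb` treats knowledge-base population as a typed, recursive
prompt-completion problem. A schema declares classes with ordered,
typed attributes; extraction of a class from a text is one
prompt-completion round, and every attribute whose range is an *inlined*
class triggers a further round on the extracted fragment. The recursion
bottoms out at primitives and at *referenced* named-entity classes, whose
values are grounded to vocabulary identifiers rather than expanded.

The model's central assumption is that a capable instruction-following
language model, given an explicit per-attribute template, will return
near-template text — but nothing stronger. Completions are therefore
parsed heuristically (line-wise, first-colon split, case-insensitive key
matching with whitespace normalized to underscores) and every deviation is
recoverable: unknown lines become skip records, ungroundable spans become
blank-node placeholders, and arbitrary bytes parse to an empty instance.
The parser is deliberately total; hallucination control comes not from
constraining the model but from validating its output against schema
constraints and external vocabularies.

Identity is handled by grounding, not generation: the model is never asked
to produce identifiers (asking tends to produce plausible fakes). Instead,
extracted spans are matched against local lexicons and the result is
validated against the class's allowed identifier prefixes and value sets.
Anything that fails validation is visibly a placeholder rather than
silently wrong — the property the whole design optimizes for.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `style` (instructions) | `"split"` | Two printed instruction variants exist; the "Split the following piece of text…" phrasing is the default because it is the one used by the fully worked single-fragment example, and recursion operates on short fragments. The multi-entity "From the text below, extract…" variant is selected per call. A fixed default with an explicit argument was preferred over auto-switching by call depth: prompt text should be predictable from the call site alone. |
| `wrap` | `TRUE` | Angle-bracket wrapping of attribute prompts, matching the printed template; can be disabled. |
| break marker | `"==="` | Three break characters demarcating the end of the input text. |
| `delimiter` | `";"` | Multivalued split token. Tokens containing the delimiter cannot be escaped; this is a documented limitation, and the fixture generators avoid embedded semicolons in nested flattened text for exactly this reason. |
| `none_values` | none, n/a, … | Right-hand sides treated as empty; common model fillers. Configurable. |
| `window`, `overlap` | 2500, 250 chars | Chunking defaults, chosen to keep prompts comfortably inside small context windows; no reference values exist for these, so they are package choices and fully configurable. Boundaries snap backward to sentence/whitespace breaks within the overlap so entities straddling a raw cut stay whole in the following chunk. |
| `temperature` | 0 | Lowest-creativity completion setting; structure extraction wants determinism, not diversity. |
| `retries` | 2 | Transport-failure retries before a backend-unavailable error. |

## Grounding policy

Lexical normalization is case folding, Unicode NFKC, whitespace collapse,
and terminal punctuation stripping. Matching is whole-span: the value
parsed out of a completion is taken to be one entity mention, not a
passage to scan. When the whole span fails, a longest-prefix fallback
drops a trailing parenthetical, then trailing tokens one at a time; such
matches are flagged (`kind = "normalized"`, truncated `matched_span`) so
the strict grounding-accuracy protocol can reject them — a term counts as
correctly grounded only if its label survived as a single, unchanged
entity mapped to exactly the right identifier.

When several lexicons propose candidates, the winner is chosen by a total
tie-break: verbatim label match first, then lexicon order, then entry
priority, then the lexicographically smallest CURIE. The rule is a
package decision (no reference ranking exists for multi-vocabulary
grounding); what matters is that it is total, so grounding is
deterministic for a fixed lexicon order, and that is property-tested
against brute-force enumeration.

Prefix constraints and value sets are both enforced when both are present
(intersection semantics — the looser reading would let a value set admit
identifiers from undeclared vocabularies). Identifier normalization across
vocabularies is a single-hop table lookup; chains are out of scope, which
keeps the offline mapping contract auditable.

Value sets are either explicit CURIE lists or branch queries
("descendants of these roots, minus descendants of those") resolved by
breadth-first reachability over a child–parent edge table. The in-package
implementation is hand-rolled and is checked in the test suite against an
independent `igraph` reachability oracle on random DAGs — the two routes
are kept separate so the library never silently becomes the
implementation.

## Numerical and structural choices

* **Cycles.** Recursion over inlined ranges terminates only on acyclic
  inlining, so cyclic inlined ranges are rejected when the schema loads,
  not guarded at runtime. Mutual *references* (non-inlined) remain legal.
* **Duplicate completion lines.** First value wins for single-valued
  attributes (with a conflict record); multivalued attributes concatenate.
* **Number coercion.** Primitive values are kept as-is unless the declared
  range is `number`/`boolean`; failed coercion keeps the string and records
  a warning rather than dropping data.
* **Chunk merging.** Multivalued attributes take the set union in
  first-seen order (structural value equality); single-valued attributes
  keep the first non-empty value and record conflicts.
* **Scoring conventions.** Precision is 0 with no predictions, recall is 0
  with an empty gold set, F is 0 when P + R = 0; predictions are
  deduplicated before matching. Triple matching is per-document by default
  (mirroring per-abstract relation benchmarks), corpus-wide via a flag.
* **Degenerate inputs.** Empty completion → empty instance; empty term
  list → accuracy `NA`, not 1; empty lexicon → every span a placeholder.

## What the synthetic corpora emulate — and what they do not

`make_fixture_corpus()` builds random instance trees for two schemas (a
nested recipe schema; a chemical-to-disease association schema with
MeSH-style value sets), renders the completions a well-behaved model would
emit for every prompt the pipeline will generate (including all recursive
prompts), and pairs them with lexicons covering every named-entity label.
By construction the corpus is deterministic under its seed and the
pipeline recovers every instance exactly — which is precisely what the
round-trip tests and the acceptance script assert, at 100 documents per
schema (a size chosen to exercise the combinatorics while keeping the
default test run fast).

This validates the machinery — prompt fidelity, parsing, recursion,
merging, grounding, scoring — not the language model. Real completions
deviate from templates in ways the mock backend cannot produce
(paraphrased keys, hallucinated attributes, merged lines), real lexicons
are incomplete and ambiguous, and real evaluation scores reflect model
quality as much as pipeline correctness. A perfect synthetic round-trip
therefore says the pipeline adds no error of its own; it says nothing
about the precision of any particular model. The handful of well-known
groundings (e.g. "garlic powder" → `FOODON:03301844`) are real; all other
fixture identifiers are synthetic and marked as such.

## Known limitations

* Whole-span grounding with a truncating fallback cannot recover entities
  embedded mid-span, and the fallback itself can produce confident
  partial matches — which the accuracy protocol deliberately scores as
  incorrect.
* Delimiter collisions in multivalued values are unescapable.
* Schema support is a small dialect: no slot inheritance, mixins, or
  cross-format schema import; value sets interact with at most one
  ontology graph.
* RDF export covers the instance graph only (typed nodes and
  attribute triples in Turtle); OWL axiomatization and reasoning are out
  of scope and belong to downstream tooling.
* The live HTTP backend is a minimal, optional adapter; nothing in the
  package or its tests depends on network access.
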