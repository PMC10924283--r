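#' Generate the extraction prompt for a class
#'
#' The prompt is a deterministic, purely textual function of the schema, the
#' target class and the input text. It is assembled, in order, from: an
#' instruction line; one template line per attribute of the class (in schema
#' order); the fixed text introducer `"Text:"`; the input text; and a break
#' marker of three break characters (`"==="`). For the recipe fixture's
#' `Ingredient` class and the text `"garlic powder (2 tablespoons)"` this
#' yields:
#'
#' ```
#' Split the following piece of text into fields in the following format:
#' food_item: <the food item>
#' amount: <the quantity of the ingredient>
#' Text:
#' garlic powder (2 tablespoons)
#' ===
#' ```
#'
#' @param schema A `pkb_schema`.
#' @param class Name of the class to instantiate.
#' @param text Input text (non-empty).
#' @param style Instruction variant: `"split"` (default; phrased for a single
#'   short fragment) or `"extract"` (phrased for multi-entity extraction from
#'   a longer passage).
#' @param wrap Wrap each attribute prompt in angle brackets (default `TRUE`).
#' @return The prompt as a single string. No backend is contacted.
#' @export
generate_prompt <- function(schema, class, text,
                            style = c("split", "extract"), wrap = TRUE) {
  style <- match.arg(style)
  cls <- schema_class(schema, class)
  if (!is_string(text) || !nzchar(text)) {
    pkb_stop("pkb_invalid_input", "input text must be a non-empty string")
  }
  paste0(
    prompt_instructions(style), "\n",
    attribute_template(schema, class, wrap = wrap),
    "Text:", "\n",
    text, "\n",
    prompt_break()
  )
}

prompt_instructions <- function(style) {
  switch(style,
    split = "Split the following piece of text into fields in the following format:",
    extract = "From the text below, extract the following entities in the following format:"
  )
}

prompt_break <- function() "==="

#' Attribute template block of a prompt
#'
#' One line per attribute of the class, in schema order:
#' `name: <prompt>`, where the prompt is the attribute's custom prompt or an
#' auto-generated one (see [auto_prompt()]). For multivalued attributes the
#' prompt is preceded with `"A semicolon-separated list of"`.
#'
#' @inheritParams generate_prompt
#' @return Template text; each line newline-terminated, empty string for a
#'   class with no attributes.
#' @export
attribute_template <- function(schema, class, wrap = TRUE) {
  cls <- schema_class(schema, class)
  if (length(cls$attributes) == 0L) return("")
  lines <- vapply(cls$attributes, function(att) {
    p <- att$prompt %||% auto_prompt(att$name)
    if (att$multivalued) p <- paste("A semicolon-separated list of", p)
    if (wrap) p <- paste0("<", p, ">")
    paste0(att$name, ": ", p)
  }, character(1L))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Auto-generate an attribute prompt from its name
#'
#' Underscores become spaces and the words are prefixed with "the", so
#' `food_item` becomes `"the food item"`.
#'
#' @param attribute_name Attribute name (non-empty).
#' @return The generated prompt text.
#' @export
auto_prompt <- function(attribute_name) {
  if (!is_string(attribute_name) || !nzchar(attribute_name)) {
    pkb_stop("pkb_invalid_input", "attribute name must be non-empty")
  }
  paste0("the ", gsub("_", " ", attribute_name, fixed = TRUE))
}
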