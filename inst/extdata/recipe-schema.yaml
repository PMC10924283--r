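name: recipe
entry_class: Recipe
prefixes:
  FOODON: http://purl.obolibrary.org/obo/FOODON_
  UO: http://purl.obolibrary.org/obo/UO_
  recipe: http://example.org/recipe/
classes:
  Recipe:
    attributes:
      label:
        range: string
      description:
        range: string
      categories:
        range: string
        multivalued: true
      steps:
        range: Step
        multivalued: true
        inlined: true
      ingredients:
        range: Ingredient
        multivalued: true
        inlined: true
  Step:
    attributes:
      action:
        range: string
      input:
        range: FoodItem
  Ingredient:
    attributes:
      food_item:
        range: FoodItem
      amount:
        range: Quantity
        inlined: true
        prompt: the quantity of the ingredient
  Quantity:
    attributes:
      value:
        range: string
      unit:
        range: Unit
  FoodItem:
    named_entity: true
    id_prefixes: [FOODON]
    attributes: {}
  Unit:
    named_entity: true
    id_prefixes: [UO]
    attributes: {}
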