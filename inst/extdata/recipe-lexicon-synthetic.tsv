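# Synthetic fixture lexicon for the recipe schema. Only the grounding of
# "garlic powder" (FOODON:03301844) is a real, well-known identifier; every
# other CURIE below is a synthetic stand-in for ontology annotator output.
curie	label	is_synonym	priority
FOODON:03301844	garlic powder	0	1
FOODON:9990001	chopped onion	0	1
FOODON:9990002	olive oil	0	1
FOODON:9990003	sea salt	0	1
FOODON:9990004	black pepper	0	1
FOODON:9990005	wheat flour	0	1
FOODON:9990006	brown sugar	0	1
FOODON:9990007	tomato paste	0	1
FOODON:9990008	fresh basil	0	1
FOODON:9990009	ground cumin	0	1
FOODON:9990010	lemon juice	0	1
FOODON:9990011	butter	0	1
FOODON:9990003	salt	1	2
UO:9990002	tablespoons	0	1
UO:9990003	teaspoons	0	1
UO:9990004	cups	0	1
UO:9990005	grams	0	1
UO:9990006	milliliters	0	1
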