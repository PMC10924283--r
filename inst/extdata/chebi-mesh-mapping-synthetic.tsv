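# Synthetic single-hop identifier mapping pairs (ChEBI-style to MeSH-style)
# standing in for a live identifier normalization service.
from	to
CHEBI:9900001	MESH:D008094
CHEBI:9900002	MESH:D005472
CHEBI:9900003	MESH:D019806
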