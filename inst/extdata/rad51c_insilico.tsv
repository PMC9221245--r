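variant_id	transcript_label	provean	revel
c.146-4_146-2del	Δ(E2p3)	-10.29	NA
c.146-3C>G	Δ(E2p3)	-10.29	NA
c.966-1G>C	▼(E8p3)	-11.94	NA
c.904G>A	FL	NA	0.5
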