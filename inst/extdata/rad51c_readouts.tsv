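variant_id	transcript_label	mean_percent	sd_percent
wild_type	FL	98.6	0.2
wild_type	1106nt	1.4	0.2
c.146-4_146-2del	Δ(E2)	73.8	0.8
c.146-4_146-2del	Δ(E2p3)	25.1	0.4
c.146-4_146-2del	657nt	1.1	0.9
c.146-3C>G	Δ(E2)	94.8	0.9
c.146-3C>G	Δ(E2p3)	5.2	0.9
c.404+2T>C	▼(E2q27)-a	77.2	1.3
c.404+2T>C	Δ(E2)	16.7	0.3
c.404+2T>C	Δ(E2q175)	4.7	0.1
c.404+2T>C	657nt	1.4	1.2
c.404+3A>G	FL	26.3	0.4
c.404+3A>G	▼(E2q27)-b	66.4	1.6
c.404+3A>G	Δ(E2q175)	5.4	0.3
c.404+3A>G	657nt	1.9	1.6
c.405-1G>C	Δ(E3p7)	48.9	1.6
c.405-1G>C	Δ(E3)	48.2	1.2
c.405-1G>C	813nt	2.9	0.3
c.571+1del	Δ(E3q1)	98.4	1.4
c.571+1del	800nt	1.6	1.4
c.572-3C>G	Δ(E4)	94.7	0.3
c.572-3C>G	1063nt	3.0	0.2
c.572-3C>G	1008nt	2.3	0.1
c.572-1G>C	Δ(E4)	93.8	0.0
c.572-1G>C	1008nt	3.2	0.0
c.572-1G>C	1063nt	1.5	0.0
c.572-1G>C	976nt	1.5	0.0
c.705+1G>A	Δ(E4)	100	0
c.705+3A>G	FL	21.3	1.3
c.705+3A>G	Δ(E4)	78.7	1.3
c.706-1G>T	Δ(E5p10)	100	0
c.837+1G>T	Δ(E5)	95.3	0.4
c.837+1G>T	976nt	4.7	0.4
c.837+4_837+7del	Δ(E5)	100	0
c.838-2A>G	Δ(E6)	98.4	1.4
c.838-2A>G	590nt	1.6	0.4
c.904G>A	FL	2.4	0.1
c.904G>A	▼(E6q4)-a	97.6	0.1
c.904+1G>T	▼(E6q4)-b	100	0
c.905-3_906del	Δ(E7)	100	0
c.905-2del	Δ(E7)	100	0
c.965+1G>A	Δ(E7)	100	0
c.966-1G>C	Δ(E8)	20.6	0.1
c.966-1G>C	▼(E8p3)	79.4	0.1
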