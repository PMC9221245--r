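domain_name	aa_start	aa_end	critical
linker	180	210	FALSE
walker_B_beta4	239	246	TRUE
beta5	260	268	TRUE
beta6	308	316	TRUE
beta7	319	327	TRUE
beta8	332	340	TRUE
beta9	349	357	TRUE
NLS	366	375	TRUE
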