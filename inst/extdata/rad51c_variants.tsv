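hgvs_c	clinvar_acc	mes_ref	mes_alt	new_site_score	new_site_offset	new_site_side	clinvar_records	prior_report	gnomad_ac	gnomad_an	pvs1	pp3
c.146-4_146-2del	VCV000482181.5	9.5	-0.8	5.9	3	downstream	3	FALSE	0	250394	PVS1	N/A
c.146-3C>G	VCV000484752.4	9.5	1.9	NA	NA	NA	2	FALSE	0	250394	N/A	PP3
c.404+2T>C	VCV000182835.10	4.8	-3.0	5.4	27	downstream	8	FALSE	1	246102	PVS1	N/A
c.404+3A>G	VCV000409857.4	4.8	0.6	5.4	27	downstream	2	FALSE	0	246102	N/A	PP3
c.405-1G>C	VCV000141823.5	7.7	-0.4	4.2	7	downstream	2	FALSE	0	251476	PVS1	N/A
c.571+1del	VCV000482176.8	10.5	-14.1	11.1	1	upstream	5	FALSE	1	251452	PVS1	N/A
c.572-3C>G	VCV000633386.5	7.4	-1.4	NA	NA	NA	2	FALSE	0	251198	N/A	PP3
c.572-1G>C	VCV000480497.10	7.4	-0.6	NA	NA	NA	6	FALSE	0	251220	PVS1	N/A
c.705+1G>A	VCV000230577.9	9.1	0.9	NA	NA	NA	4	FALSE	0	251038	PVS1	N/A
c.705+3A>G	VCV000241775.7	9.1	4.6	6.1	2	downstream	3	FALSE	0	250946	N/A	PP3
c.706-1G>T	VCV000452310.4	11.1	2.5	4.3	10	downstream	2	FALSE	0	282746	PVS1	N/A
c.837+1G>T	VCV000241779.3	8.6	0.1	NA	NA	NA	2	FALSE	0	251374	PVS1	N/A
c.837+4_837+7del	VCV000128212.8	8.6	-8.9	NA	NA	NA	5	FALSE	0	251374	N/A	PP3
c.838-2A>G	VCV000480508.3	10.2	2.2	NA	NA	NA	2	FALSE	0	250982	PVS1	N/A
c.904G>A	VCV000478781.9	5.6	1.0	6.2	4	downstream	4	FALSE	0	250832	N/A	PP3
c.904+1G>T	VCV000480510.7	5.6	-3.0	6.2	4	downstream	3	FALSE	0	250832	PVS1	N/A
c.905-3_906del	VCV000182846.7	8.2	-8.6	4.5	7	downstream	3	FALSE	0	282730	PVS1	N/A
c.905-2del	VCV000230587.7	8.2	2.1	NA	NA	NA	3	FALSE	0	282730	PVS1	N/A
c.965+1G>A	VCV000182838.5	8.7	0.5	NA	NA	NA	2	FALSE	0	251118	PVS1	N/A
c.966-1G>C	VCV000851327.3	7.3	-0.8	6.8	3	upstream	2	FALSE	0	251358	PVS1	N/A
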