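gene_id	weight	direction	note
LAMP2A	2	1	lysosomal receptor, rate-limiting CMA component
HSPA8	1	1	hsc70 chaperone, substrate targeting
HSP90AA1	1	1	chaperone, stabilizes LAMP2A translocation complex
HSPA4	1	1	co-chaperone (hsp110 family)
DNAJB1	1	1	hsp40 co-chaperone
BAG1	1	1	nucleotide exchange factor, substrate release
STUB1	1	1	CHIP co-chaperone
NFE2L2	1	1	NRF2, transcriptional activator of LAMP2A
PHLPP1	1	1	phosphatase, counteracts inhibitory AKT signaling
NFATC3	1	1	calcineurin/NFAT effector, transcriptional activation
RAB11A	1	1	endosomal trafficking supporting LAMP2A turnover
GFAP	1	-1	stabilizes inactive translocation complex
EEF1A2	1	-1	releases GFAP inhibition upon GTP binding
RARA	1	-1	retinoic acid receptor alpha, transcriptional repressor of CMA
MTOR	1	-1	TORC2 inhibitory signaling at the lysosome
AKT1	1	-1	phosphorylates GFAP, inhibits translocation
CTSA	1	-1	protease mediating LAMP2A degradation
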