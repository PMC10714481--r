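gene	chrom	start	end	proxy_trait	eligible
LDLR	19	11200038	11244492	LDL-C	TRUE
HMGCR	5	74632154	74657929	LDL-C	TRUE
ACLY	17	40023161	40086795	LDL-C	FALSE
PCSK9	1	55505221	55530525	LDL-C	TRUE
NPC1L1	7	44552134	44580914	LDL-C	TRUE
APOB	2	21224301	21266945	LDL-C	TRUE
CETP	16	56995762	57017757	LDL-C	TRUE
LPL	8	19759228	19824769	TG	TRUE
PPARA	22	46546424	46639653	TG	FALSE
ANGPTL3	1	63063158	63071830	TG	TRUE
APOC3	11	116700422	116703788	TG	TRUE
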