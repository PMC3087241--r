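# Reference RLBH probe panel (13 group-specific 16S-23S ITS probes) and the
# PCR primers of the assay; published melting temperatures are metadata.
name	type	sequence	tm_published	biotinylated
F1	probe	CTAAGCGATTGTTAATTGTTTAGT	54.2	FALSE
F2	probe	TTATAAAGTTCTTAAATAGTACTTAAAGT	54.0	FALSE
F4	probe	ACCATCAGCAGCAGTGATA	54.5	FALSE
F5	probe	CCACCAATCAGCGTTGATA	54.5	FALSE
F10	probe	ACTAAGCGATCTAATGATTGTTTA	54.2	FALSE
F11	probe	MAGTGATATGGACTAWGTGG	54.2	FALSE
F12	probe	CCACCAATCAGCAGTGATA	54.5	FALSE
F13n	probe	CTAAGACCATATCACTACTGA	54.5	FALSE
F14	probe	ACTAAGCGATCTATTGATTGTTTA	54.2	FALSE
F15	probe	ACTAAGCAATTTAGCGATTGTTTA	54.2	FALSE
F15-1	probe	CCAAACTGTAAGTACTTATTAAAG	54.2	FALSE
F16	probe	GACCCACCAAATCAGAAGT	54.4	FALSE
F17	probe	CAAAACTAAGCGAAGACTTAATCGTTTAGTT	54.7	FALSE
PnecCf-4	primer	CACACTTATCGGTTGACAATAA	NA	FALSE
PnecCr-5-BIO	primer	AACGAGCACCATTGCTAGY	NA	TRUE
PnecC441f	primer	GTCAGGGAAGAAACACCG	NA	FALSE
Poly23Sr	primer	GCTACTTAGATGTTTCAGTTCAC	NA	FALSE
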