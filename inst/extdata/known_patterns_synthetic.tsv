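# Synthetic stand-in catalogue of known in situ patterns, 16-cell stage.
# Columns: gene_id, then 8 bits in canonical cell-type order
# (a5.3 a5.4 b5.3 b5.4 A5.1 A5.2 B5.1 B5.2) or the word 'unknown';
# optional trailing column: comma-separated alternate acceptable patterns.
# Gene-to-pattern assignments are illustrative stand-ins except where
# attested in the text (Foxa.a anterior; B5.2-only postplasmic genes).
Foxa.a	1	1	0	0	1	1	0	0
Hes.a	1	1	1	1	1	1	1	0
Pem-1	0	0	0	0	0	0	0	1
Zf266	0	0	0	0	0	0	0	1
KH.C13.98	0	0	0	0	0	0	0	1
KH.C12.212	0	0	0	0	0	0	0	1
Tbx6-r.b	0	0	0	0	0	0	1	1	00000001
Wnt5	0	0	0	0	0	0	1	1
Fgf9/16/20	0	0	0	0	1	1	1	0
Lefty	0	0	0	0	1	1	1	1
Foxd	0	0	0	0	1	1	1	1
Neurog	1	1	1	1	0	0	0	0
Prdm1-r	0	0	1	1	0	0	1	1
Otx	1	1	0	0	1	1	0	0
KH.L152.12	unknown
KH.S1497.1	unknown
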