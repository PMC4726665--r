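study	n_total	n_high	n_low	outliers_total	outliers_high	outliers_low	platform	tissue
GSE56815	80	40	40	3	2	1	HG-U133A	peripheral blood monocytes
GSE7158	26	14	12	2	2	0	HG-U133_Plus_2	peripheral blood monocytes
GSE2208	19	10	9	0	0	0	HG-U133A	peripheral blood monocytes
E-MEXP-1618	84	45	39	4	1	3	HG-U133_Plus_2	bone biopsies
GSE7429	20	10	10	3	2	1	HG-U133A	circulating B cells
GSE13850	20	10	10	1	0	1	HG-U133A	circulating B cells
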