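gene	smd	smd_se	z	es_p	fisher_stat	fisher_p	gwas_p_gefos2	gwas_p_meta7
ESR1	0.49	0.24	2.05	2.67e-02	31.81	1.48e-03	1.13e-11	2.52e-07
MAP3K3	-0.53	0.28	-1.90	3.95e-02	46.93	4.79e-06	2.25e-02	2.65e-02
PYGM	-0.70	0.13	-5.17	2.25e-07	42.85	2.40e-05	2.67e-03	6.67e-04
RAC1	-0.45	0.25	-1.76	5.50e-02	40.90	5.10e-05	2.74e-02	4.41e-02
SYK	0.52	0.26	1.99	3.13e-02	49.72	1.57e-06	2.51e-03	3.84e-02
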