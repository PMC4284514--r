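mirna_id	control_mean	control_sd	treated_mean	treated_sd	ratio_printed
miR-105-2	18526.7	10013.5	459.3	211.2	0.02
miR-877	5736.8	1938.1	195.0	29.9	0.03
let-7f	941.8	351.1	57.3	27.1	0.06
miR-125a	53507.6	16213.9	3788.5	381.2	0.07
miR-574-3p	136.9	6.3	22.0	4.3	0.16
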