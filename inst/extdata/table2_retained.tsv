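mirna_id	control_mean	control_sd	treated_mean	treated_sd	ratio_printed
miR-134	1534.9	350.9	16522.6	8601.0	10.76
miR-549	8430.7	4832.2	54010.0	9153.1	6.41
Let-7a-3	3993.8	1157.2	24562.5	14098.6	6.15
miR-605	4200.2	319.0	24924.5	13551.3	5.93
miR-891b	123.6	49.2	720.0	370.9	5.82
miR-892	5339.9	573.2	27856.3	1230.8	5.22
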