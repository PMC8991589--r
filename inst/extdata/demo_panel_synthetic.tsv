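snp_id	maf	log_or	ld_block	target_r2
snp01	0.38	0.18	b1	0.5
snp02	0.38	0.11	b1	0.5
snp03	0.12	-0.14	NA	NA
snp04	0.26	0.22	NA	NA
snp05	0.47	0.08	NA	NA
snp06	0.3	0.16	NA	NA
snp07	0.22	-0.1	NA	NA
snp08	0.41	0.13	NA	NA
snp09	0.16	0.2	NA	NA
snp10	0.49	0.06	NA	NA
snp11	0.28	-0.12	NA	NA
snp12	0.09	0.26	NA	NA
snp13	0.33	0.09	b2	0.3
snp14	0.44	0.15	NA	NA
snp15	0.19	-0.08	NA	NA
snp16	0.33	0.19	b2	0.3
snp17	0.25	0.1	NA	NA
snp18	0.13	0.24	NA	NA
snp19	0.4	0.07	NA	NA
snp20	0.31	-0.11	NA	NA
snp21	0.21	0.14	NA	NA
snp22	0.46	0.05	NA	NA
snp23	0.17	0.21	NA	NA
snp24	0.29	0.12	NA	NA
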