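# Shared-SNP counts between the Illumina BovineHD panel and lower-density
# chips in a Nelore imputation study design: number of markers each chip
# shares with the HD chip, before and after HD quality control.
label	n_common_hd	n_common_after_qc
HD	777962	439595
7K	6637	4086
50K	49345	21014
GGP20Ki	19493	13450
GGP75Ki	73941	56169
15K_e	15144	15144
15K_em	15173	15173
15K_el	15173	15173
15K_eml	15173	15173
11a7K	17841	15290
17a7K	24121	21570
27a7K	33942	31391
48a7K	55141	52590
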