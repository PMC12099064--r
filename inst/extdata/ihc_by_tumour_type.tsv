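ihc_class	sebaceoma	adenoma	carcinoma
MMRd	14	32	3
equivocal	0	0	3
MMRp	18	27	7
NA	1	2	0
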