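pattern	ihc_class	mss	uncertain	msih
MSH2/MSH6/MLH1/PMS2 loss	MMRd	0	0	1
MSH2/MSH6/PMS2 loss	MMRd	0	0	1
MSH2/MSH6 loss	MMRd	1	0	26
MSH2 eq., MSH6 loss	MMRd	0	1	0
MSH6 loss	MMRd	2	0	1
MLH1/PMS2 loss	MMRd	1	0	5
MLH1 eq., PMS2 loss	MMRd	4	0	5
PMS2 loss	MMRd	0	0	1
MLH1/PMS2 eq.	equivocal	1	0	0
PMS2 eq.	equivocal	2	0	0
Retained	MMRp	52	0	0
Uninterpretable	NA	1	0	2
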