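gene	genorm_m	normfinder_stability	bestkeeper_r
PUM1	0.160	0.255	0.606
PPIA	0.599	0.330	0.944
18S	0.160	0.299	0.372
ACTB	0.475	0.207	0.053
HPRT-1	0.540	0.239	0.625
GAPDH	0.314	0.462	0.729
B2M	0.808	0.601	0.870
ALAS1	0.662	0.473	0.855
PBGD	0.741	0.418	0.548
TBP	0.925	0.660	0.193
RPL-29	1.027	0.744	NA
GUSB	1.035	0.948	NA
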