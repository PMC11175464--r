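channel	x	y
F7	-1.5	1.5
F3	-0.5	1.5
F4	0.5	1.5
F8	1.5	1.5
FC5	-1.5	0.5
FC1	-0.5	0.5
FC2	0.5	0.5
FC6	1.5	0.5
CP5	-1.5	-0.5
CP1	-0.5	-0.5
CP2	0.5	-0.5
CP6	1.5	-0.5
P7	-1.5	-1.5
P3	-0.5	-1.5
P4	0.5	-1.5
P8	1.5	-1.5
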