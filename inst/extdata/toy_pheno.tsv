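subject	phenotype	age	sex
s1	1	34.5	1
s2	1	40.1	0
s3	0	29.9	1
s4	1	51.2	0
s5	0	45.0	1
s6	0	38.7	0
s7	1	47.3	1
s8	0	33.1	0
s9	1	36.8	1
s10	0	42.6	0
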