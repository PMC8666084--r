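chr1	0	10000000	p36	gneg
chr1	10000000	30000000	p35	gpos50
chr1	30000000	60000000	q11	gneg
chr2	0	20000000	p12	gneg
chr2	20000000	50000000	q13	gvar
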