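subject	chrom	start	end	type	dosage
s1	chr1	1000001	1200000	del	1
s1	chr1	25000001	25400000	amp	4
s2	chr1	1050001	1250000	del	0
s2	chr2	21000001	21500000	amp	3
s3	chr1	25100001	25500000	amp	5
s4	chr2	5000001	5600000	del	1
s4	chr2	21200001	21700000	amp	6
s5	chr1	1000001	1200000	del	1
s5	chr1	40000001	40800000	amp	3
s6	chr2	5050001	5650000	del	0
s7	chr1	25000001	25400000	amp	7
s7	chr2	21000001	21500000	amp	3
s8	chr1	40100001	40900000	amp	4
s9	chr2	5000001	5600000	del	1
s10	chr1	1100001	1300000	del	0
s10	chr2	44000001	44500000	amp	3
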