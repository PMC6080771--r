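chr1	95	102	read1	0	+
chr1	95	135	read2	0	+
chr1	95	165	read3	0	+
chr1	155	195	read4	0	+
chr1	155	225	read5	0	+
chr1	215	222	read6	0	+
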