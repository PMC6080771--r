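chrom	pos0
chr1	100
chr1	130
chr1	160
chr1	190
chr1	220
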