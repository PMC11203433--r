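exon_id	cdna_start	cdna_end
1	1	12
2	13	24
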