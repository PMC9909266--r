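name,role,sequence,tm,gc_printed
me1,forward,TGAGTCCAAACCGGATA,48.8,47.1
me2,forward,TGAGTCCAAACCGGAGC,54.7,58.8
me3,forward,TGAGTCCAAACCGGAAT,49.8,47.1
me4,forward,TGAGTCCAAACCGGACC,54.4,58.8
me5,forward,TGAGTCCAAACCGGAAG,51.2,52.9
me6,forward,TGAGTCCAAACCGGACA,52.9,52.9
em1,reverse,GACTGCGTACGAATTAAT,45.6,38.9
em2,reverse,GACTGCGTACGAATTTGC,51.3,50.0
em3,reverse,GACTGCGTACGAATTGAC,50.4,50.0
em4,reverse,GACTGCGTACGAATTTGA,49.0,44.4
em6,reverse,GACTGCGTACGAATTGCA,52.5,50.0
ba1,reverse,GTCGAGCTGCCAATTATA,48.3,44.4
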