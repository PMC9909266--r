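name,sequence,tm,gc_printed
SCoT 1,CAACAATGGCTACCACCA,52.0,50
SCoT 2,CAACAATGGCTACCACCC,53.5,55.6
SCoT 3,CAACAATGGCTACCACCG,53.7,55.6
SCoT 4,CAACAATGGCTACCACCT,51.8,50.0
SCoT 5,CAACAATGGCTACCACGA,52.0,50.0
SCoT 6,CAACAATGGCTACCACGC,54.3,55.6
SCoT 7,CAACAATGGCTACCACGG,53.7,55.6
SCoT 8,CAACAATGGCTACCACGT,52.3,50.0
SCoT 13,ACGACATGGCGACCATCG,58.3,61.1
SCoT 16,ACCATGGCTACCACCGAC,57.5,61.1
SCoT 30,CCATGGCTACCACCGGCG,62.8,72.2
SCoT 33,CCATGGCTACCACCGCAG,59.5,66.7
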