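codon	count
TTT	600
TTC	400
TTA	200
TTG	133
TCT	200
TCC	133
TCA	200
TCG	133
TAT	600
TAC	400
TGT	600
TGC	400
TGG	1000
CTT	200
CTC	133
CTA	200
CTG	133
CCT	300
CCC	200
CCA	300
CCG	200
CAT	600
CAC	400
CAA	600
CAG	400
CGT	200
CGC	133
CGA	200
CGG	133
ATT	375
ATC	250
ATA	375
ATG	1000
ACT	300
ACC	200
ACA	300
ACG	200
AAT	600
AAC	400
AAA	600
AAG	400
AGT	200
AGC	133
AGA	200
AGG	133
GTT	300
GTC	200
GTA	300
GTG	200
GCT	300
GCC	200
GCA	300
GCG	200
GAT	600
GAC	400
GAA	600
GAG	400
GGT	300
GGC	200
GGA	300
GGG	200
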