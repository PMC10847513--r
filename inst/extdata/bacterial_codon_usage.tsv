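codon	count
TTT	300
TTC	700
TTA	100
TTG	233
TCT	100
TCC	233
TCA	100
TCG	233
TAT	300
TAC	700
TGT	300
TGC	700
TGG	1000
CTT	100
CTC	233
CTA	100
CTG	233
CCT	150
CCC	350
CCA	150
CCG	350
CAT	300
CAC	700
CAA	300
CAG	700
CGT	100
CGC	233
CGA	100
CGG	233
ATT	231
ATC	538
ATA	231
ATG	1000
ACT	150
ACC	350
ACA	150
ACG	350
AAT	300
AAC	700
AAA	300
AAG	700
AGT	100
AGC	233
AGA	100
AGG	233
GTT	150
GTC	350
GTA	150
GTG	350
GCT	150
GCC	350
GCA	150
GCG	350
GAT	300
GAC	700
GAA	300
GAG	700
GGT	150
GGC	350
GGA	150
GGG	350
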