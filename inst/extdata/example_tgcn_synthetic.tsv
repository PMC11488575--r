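anticodon	copies
AGC	11
TGC	5
ACG	6
CCG	1
CCT	1
TCT	11
GTT	10
GTC	16
GCA	4
TTG	9
CTG	1
TTC	14
CTC	2
GCC	16
CCC	2
GTG	7
GAT	13
TAT	2
TAG	3
GAG	1
TAA	7
CAA	10
TTT	7
CTT	14
CAT	10
GAA	10
TGG	10
AGA	11
TGA	3
CGA	1
AGT	11
CGT	4
TGT	2
CCA	6
GTA	8
AAC	14
TAC	2
CAC	2
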