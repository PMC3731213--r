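MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.29500 C 0.20500 G 0.20500 T 0.29500

MOTIF toyA
letter-probability matrix: alength= 4 w= 6
0.820000 0.060000 0.060000 0.060000
0.060000 0.820000 0.060000 0.060000
0.060000 0.060000 0.820000 0.060000
0.820000 0.060000 0.060000 0.060000
0.060000 0.060000 0.060000 0.820000
0.820000 0.060000 0.060000 0.060000

MOTIF toyB
letter-probability matrix: alength= 4 w= 5
0.060000 0.060000 0.820000 0.060000
0.060000 0.820000 0.060000 0.060000
0.060000 0.060000 0.820000 0.060000
0.060000 0.820000 0.060000 0.060000
0.060000 0.060000 0.820000 0.060000
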