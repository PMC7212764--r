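MEME version 4

ALPHABET= ACGT

strands: + -

background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF synthetic-crz1-like
letter-probability matrix: alphabet length= 4 w= 8 nsites= 100 E= 0
 0.05 0.05 0.85 0.05
 0.85 0.05 0.05 0.05
 0.05 0.05 0.85 0.05
 0.05 0.05 0.85 0.05
 0.05 0.85 0.05 0.05
 0.05 0.05 0.05 0.85
 0.05 0.85 0.05 0.05
 0.85 0.05 0.05 0.05
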