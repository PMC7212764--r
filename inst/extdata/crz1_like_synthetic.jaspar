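>synthetic-crz1-like CRZ1/CDRE-like synthetic fixture (not a database matrix)
A  [  5  85   5   5   5   5   5  85 ]
C  [  5   5   5   5  85   5  85   5 ]
G  [ 85   5  85  85   5   5   5   5 ]
T  [  5   5   5   5   5  85   5   5 ]
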