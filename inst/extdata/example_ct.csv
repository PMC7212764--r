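strain,condition,gene,replicate,ct
WT,glycerol,actb,1,15.1
WT,glycerol,actb,2,15.0
WT,glycerol,actb,3,14.9
WT,glycerol,cel7a,1,24.2
WT,glycerol,cel7a,2,23.9
WT,glycerol,cel7a,3,23.9
WT,scb,actb,1,15.2
WT,scb,actb,2,15.0
WT,scb,actb,3,14.8
WT,scb,cel7a,1,20.1
WT,scb,cel7a,2,19.9
WT,scb,cel7a,3,20.0
dcrz1,glycerol,actb,1,15.0
dcrz1,glycerol,actb,2,15.1
dcrz1,glycerol,actb,3,15.2
dcrz1,glycerol,cel7a,1,24.0
dcrz1,glycerol,cel7a,2,24.1
dcrz1,glycerol,cel7a,3,23.8
dcrz1,scb,actb,1,15.1
dcrz1,scb,actb,2,14.9
dcrz1,scb,actb,3,15.0
dcrz1,scb,cel7a,1,22.4
dcrz1,scb,cel7a,2,22.2
dcrz1,scb,cel7a,3,22.6
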