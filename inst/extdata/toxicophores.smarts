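# Default structural-alert (toxicophore) screen, one SMARTS per line.
# A small set of widely used alerts; replace via reward.toxicophore_file.
# nitro group
[NX3](=O)=O
[N+](=O)[O-]
# nitroso
[NX2]=O
# N-nitroso
N[NX2]=O
# azo
N=N
# acyl halide
C(=O)[F,Cl,Br,I]
# aldehyde
[CX3H1](=O)[#6]
# epoxide / aziridine
C1OC1
C1NC1
# hydrazine
[NX3][NX3]
# isocyanate
N=C=O
# michael-acceptor enone
C=CC(=O)[#6]
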