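>AP2like_synthetic
A  [ 2 1 1 6 5 6 1 1 2 ]
C  [ 3 14 14 4 4 3 1 2 12 ]
G  [ 11 2 2 4 5 4 15 14 3 ]
T  [ 2 1 1 4 4 5 1 1 1 ]
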