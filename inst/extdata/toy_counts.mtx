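%%MatrixMarket matrix coordinate integer general
3 5 6
1 1 4
1 3 1
2 2 3
2 5 2
3 3 5
3 4 1
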