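
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    -1   5   0  -2  -3   1   0  -2  -1  -3  -2   2  -1  -3  -1   0  -1  -3  -2  -3    2  40   4   1   0   6   4   1   1   0   1  24   1   0   2   5   3   0   1   1  0.46 0.21
    2 K    -1   2   0  -1  -3   1   1  -2  -1  -3  -2   5  -1  -3  -1   0  -1  -3  -2  -2    3  10   4   3   0   6   7   2   1   1   2  47   1   0   2   5   3   0   1   2  0.59 0.23
    3 L    -1  -2  -3  -4  -1  -2  -3  -4  -3   2   4  -2   2   0  -3  -2  -1  -2  -1   1    3   2   1   0   1   2   1   1   1  12  49   2   6   3   1   2   4   1   2   9  0.67 0.25
    4 V     0  -3  -3  -3  -1  -2  -2  -3  -3   3   1  -2   1  -1  -2  -2   0  -3  -1   4    6   1   1   1   1   2   3   1   0  20  10   2   4   2   2   3   5   0   2  34  0.55 0.24
    5 T     0  -1   0  -1  -1  -1  -1  -2  -2  -1  -1  -1  -1  -2  -1   1   5  -2  -2   0    6   3   4   3   1   3   4   2   1   3   5   4   1   1   2  12  40   0   1   6  0.44 0.22
    6 G     0  -2   0  -1  -3  -2  -2   6  -2  -4  -4  -2  -3  -3  -2   0  -2  -2  -3  -3    7   2   4   3   0   2   3  65   1   0   1   2   0   1   2   5   2   0   1   1  1.12 0.28
    7 A     4  -1  -2  -2  -1  -1  -1   0  -2  -1  -1  -1  -1  -2  -1   1   0  -3  -2   0   55   3   2   2   1   3   4   5   1   3   5   4   1   1   2   8   4   0   1   5  0.61 0.24

                      K         Lambda
Standard Ungapped    0.1347     0.3179
Standard Gapped      0.0410     0.2670
PSI Ungapped         0.1550     0.3176
PSI Gapped           0.0408     0.2698
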