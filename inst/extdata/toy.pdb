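ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N
ATOM      5  CA  GLY A   2       3.988   2.839   0.000  1.00  0.00           C
ATOM      6  CA  SER B   1       7.100   2.100   1.500  1.00  0.00           C
ATOM      7  OG  SER B   1       8.250   2.900   1.900  1.00  0.00           O
HETATM    8  C1  EGC L   1      11.000   5.000   2.000  1.00  0.00           C
HETATM    9  O1  EGC L   1      12.200   5.600   2.300  1.00  0.00           O
END
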