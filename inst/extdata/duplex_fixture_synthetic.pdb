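REMARK synthetic two-chain duplex fixture for load_pdb tests
REMARK hand-written coordinates; not a real structure
ATOM      1  P    DA A   1       0.000   9.400   0.000  1.00  0.00           P
ATOM      2  O5'  DA A   1       1.000   9.400   1.000  1.00  0.00           O
ATOM      3  C4'  DA A   1       2.000   9.400   2.000  1.00  0.00           C
ATOM      4  N9   DA A   1      50.000  50.000  50.000  1.00  0.00           N
ATOM      5  P    DT A   2       5.527   7.606   3.400  1.00  0.00           P
ATOM      6  O5'  DT A   2       6.527   7.606   4.400  1.00  0.00           O
ATOM      7  P    DT B   1       0.000  -9.400   0.000  1.00  0.00           P
ATOM      8  O5'  DT B   1      -1.000  -9.400   1.000  1.00  0.00           O
ATOM      9  P    DA B   2      -5.527  -7.606   3.400  1.00  0.00           P
ATOM     10  O5'  DA B   2      -6.527  -7.606   4.400  1.00  0.00           O
ATOM     11  C3'  DA B   2      -7.527  -7.606   5.400  1.00  0.00           C
END
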