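ATOM      1  CA  ALA A   1       2.300   0.000   0.000  1.00 10.00           C
ATOM      2  CA  ALA A   2      -0.399   2.265   1.500  1.00 14.21           C
ATOM      3  CA  ALA A   3      -2.161  -0.787   3.000  1.00 14.55           C
ATOM      4  CA  ALA A   4       1.150  -1.992   4.500  1.00 10.71           C
ATOM      5  CA  ALA A   5       1.762   1.478   6.000  1.00 13.78           C
ATOM      6  CA  ALA A   6      -1.762   1.478   7.500  1.00 14.79           C
ATOM      7  CA  ALA A   7      -1.150  -1.992   9.000  1.00 11.40           C
ATOM      8  CA  ALA A   8       2.161  -0.787  10.500  1.00 13.28           C
ATOM      9  CA  ALA A   9       0.399   2.265  12.000  1.00 14.95           C
ATOM     10  CA  ALA A  10      -2.300   0.000  13.500  1.00 12.06           C
ATOM     11  CA  ALA A  11       0.399  -2.265  15.000  1.00 12.72           C
ATOM     12  CA  ALA A  12       2.161   0.787  16.500  1.00 15.00           C
ATOM     13  CA  ALA A  13      -1.150   1.992  18.000  1.00 12.68           C
ATOM     14  CA  ALA A  14      -1.762  -1.478  19.500  1.00 12.10           C
ATOM     15  CA  ALA A  15       1.762  -1.478  21.000  1.00 14.95           C
ATOM     16  CA  ALA A  16       1.150   1.992  22.500  1.00 13.25           C
ATOM     17  CA  ALA A  17      -2.161   0.787  24.000  1.00 11.44           C
ATOM     18  CA  ALA A  18      -0.399  -2.265  25.500  1.00 14.81           C
ATOM     19  CA  ALA A  19       2.300  -0.000  27.000  1.00 13.75           C
ATOM     20  CA  ALA A  20      -0.399   2.265  28.500  1.00 10.75           C
ATOM     21  CA  ALA A  21      -2.161  -0.787  30.000  1.00 14.56           C
ATOM     22  CA  ALA A  22       1.150  -1.992  31.500  1.00 14.18           C
ATOM     23  CA  ALA A  23       1.762   1.478  33.000  1.00 10.04           C
ATOM     24  CA  ALA A  24      -1.762   1.478  34.500  1.00 14.23           C
ATOM     25  CA  ALA A  25      -1.150  -1.992  36.000  1.00 14.53           C
ATOM     26  CA  ALA A  26       2.161  -0.787  37.500  1.00 10.66           C
ATOM     27  CA  ALA A  27       0.399   2.265  39.000  1.00 13.81           C
ATOM     28  CA  ALA A  28      -2.300  -0.000  40.500  1.00 14.78           C
ATOM     29  CA  ALA A  29       0.399  -2.265  42.000  1.00 11.35           C
ATOM     30  CA  ALA A  30       2.161   0.787  43.500  1.00 13.32           C
ATOM     31  CA  ALA A  31      -1.150   1.992  45.000  1.00 14.94           C
ATOM     32  CA  ALA A  32      -1.762  -1.478  46.500  1.00 12.02           C
ATOM     33  CA  ALA A  33       1.762  -1.478  48.000  1.00 12.76           C
ATOM     34  CA  ALA A  34       1.150   1.992  49.500  1.00 15.00           C
ATOM     35  CA  ALA A  35      -2.161   0.787  51.000  1.00 12.65           C
ATOM     36  CA  ALA A  36      -0.399  -2.265  52.500  1.00 12.14           C
ATOM     37  CA  ALA A  37       2.300  -0.000  54.000  1.00 14.96           C
ATOM     38  CA  ALA A  38      -0.399   2.265  55.500  1.00 13.22           C
ATOM     39  CA  ALA A  39      -2.161  -0.787  57.000  1.00 11.48           C
ATOM     40  CA  ALA A  40       1.150  -1.992  58.500  1.00 14.82           C
END
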