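@<TRIPOS>MOLECULE
*****
 24 24 0 0 0
SMALL
GASTEIGER

@<TRIPOS>ATOM
      1 C          -2.4961   -1.9515    0.8796 C.3     1  UNL1        0.0790
      2 O          -2.7267   -0.5977    0.5194 O.3     1  UNL1       -0.4915
      3 C          -1.6597    0.1192    0.0447 C.ar    1  UNL1        0.1615
      4 C          -0.3732   -0.3918   -0.1551 C.ar    1  UNL1       -0.0128
      5 C           0.6598    0.4249   -0.6511 C.ar    1  UNL1       -0.0400
      6 C           2.0473   -0.1406   -0.8487 C.3     1  UNL1       -0.0096
      7 C           2.8111   -0.2405    0.4414 C.2     1  UNL1       -0.0868
      8 C           3.3079   -1.3802    0.9403 C.2     1  UNL1       -0.1023
      9 C           0.3916    1.7700   -0.9362 C.ar    1  UNL1       -0.0546
     10 C          -0.8880    2.2902   -0.7433 C.ar    1  UNL1       -0.0163
     11 C          -1.9029    1.4657   -0.2578 C.ar    1  UNL1        0.1585
     12 O          -3.1598    1.9778   -0.0687 O.3     1  UNL1       -0.5033
     13 H          -3.4381   -2.3629    1.2552 H       1  UNL1        0.0660
     14 H          -1.7569   -2.0273    1.6840 H       1  UNL1        0.0660
     15 H          -2.1979   -2.5461    0.0099 H       1  UNL1        0.0660
     16 H          -0.1405   -1.4279    0.0701 H       1  UNL1        0.0658
     17 H           1.9659   -1.1183   -1.3407 H       1  UNL1        0.0355
     18 H           2.6119    0.4954   -1.5419 H       1  UNL1        0.0355
     19 H           2.9644    0.6858    0.9918 H       1  UNL1        0.0570
     20 H           3.8516   -1.3827    1.8802 H       1  UNL1        0.0532
     21 H           3.1842   -2.3303    0.4302 H       1  UNL1        0.0532
     22 H           1.1791    2.4204   -1.3106 H       1  UNL1        0.0622
     23 H          -1.0748    3.3343   -0.9734 H       1  UNL1        0.0655
     24 H          -3.1602    2.9138   -0.3192 H       1  UNL1        0.2923
@<TRIPOS>BOND
     1     1     2    1
     2     2     3    1
     3     3     4   ar
     4     4     5   ar
     5     5     6    1
     6     6     7    1
     7     7     8    2
     8     5     9   ar
     9     9    10   ar
    10    10    11   ar
    11    11    12    1
    12    11     3   ar
    13     1    13    1
    14     1    14    1
    15     1    15    1
    16     4    16    1
    17     6    17    1
    18     6    18    1
    19     7    19    1
    20     8    20    1
    21     8    21    1
    22     9    22    1
    23    10    23    1
    24    12    24    1
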