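[Molden Format]
[FREQ]
845.0
1231.6
1252.4
1297.1
1326.9
1655.2
[FR-COORD]
 C  0.0  0.0   0.0
 C  0.0  0.0   7.2
 C  0.0  0.0  14.4
 C  0.0  0.0  21.6
 C  0.0  0.0  28.8
 C  0.0  0.0  36.0
[FR-NORM-COORD]
vibration 1
 0.0 0.0 0.1
 0.0 0.0 0.0
 0.0 0.0 0.0
 0.0 0.0 0.0
 0.0 0.0 0.0
 0.0 0.0 0.0
vibration 2
 0.000000000 0.0 0.0
 -0.082962201 0.0 0.0
 0.034172154 0.0 0.0
 -0.021974358 0.0 0.0
 -0.038297058 0.0 0.0
 0.000000000 0.0 0.0
vibration 3
 0.000000000 0.0 0.0
 0.010514938 0.0 0.0
 -0.008577524 0.0 0.0
 -0.095964408 0.0 0.0
 0.024631172 0.0 0.0
 0.000000000 0.0 0.0
vibration 4
 0.000000000 0.0 0.0
 -0.018756963 0.0 0.0
 0.054007631 0.0 0.0
 0.013872665 0.0 0.0
 0.080863473 0.0 0.0
 0.000000000 0.0 0.0
vibration 5
 0.000000000 0.0 0.0
 -0.051525582 0.0 0.0
 -0.076432099 0.0 0.0
 0.010747521 0.0 0.0
 0.037252375 0.0 0.0
 0.000000000 0.0 0.0
vibration 6
 0.0 0.0 0.0
 0.0 0.0 0.0
 0.0 0.0 0.0
 0.0 0.0 0.0
 0.0 0.0 0.0
 0.1 0.0 0.0
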