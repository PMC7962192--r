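H SYNT000101
D Synthetic example property 1 (format demonstration; values are made up)
R
A Example
T Example AAindex1-format record for parser tests
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.100  -0.500   0.300  -0.200   0.700   0.000  -0.100   0.400   0.250   0.900
    0.800  -0.450   0.600   0.950  -0.300   0.050   0.150   1.000   0.500   0.850
//
H SYNT000201
D Synthetic example property 2 (format demonstration; values are made up)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -1.000   2.000   0.000   1.500  -0.500   0.250   0.750  -0.250   0.125   0.375
    0.625  -0.875   1.125  -1.375   1.625   0.875  -0.625   0.500  -0.750   1.250
//
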