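# PWM probabilities; columns A C G T
0.20 0.40 0.17 0.23
0.27 0.26 0.22 0.25
0.24 0.28 0.21 0.27
0.46 0.44 0.04 0.06
0.02 0.02 0.94 0.02
0.02 0.94 0.02 0.02
0.03 0.92 0.02 0.03
0.28 0.30 0.20 0.22
0.04 0.90 0.02 0.04
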