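pulse,time_h,control_exv,control_not,treated_exv,treated_not,printed_p
5000,0,18,34,34,4,<0.001
5000,4,27,32,46,18,0.003
5000,24,49,14,21,26,<0.001
125x40,0,33,36,43,9,<0.001
125x40,4,22,41,27,18,0.012
125x40,24,43,37,28,34,0.400
500x10,0,38,20,50,2,<0.001
500x10,4,20,19,40,14,0.029
500x10,24,40,37,46,28,0.250
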