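pulse,time_h,delta_photons_mean,delta_photons_sd,p_value,norm_control_mean,norm_control_sd,norm_treated_mean,norm_treated_sd
5000,0,1184,739,<0.001,1,0,1.434,0.308
5000,4,810,772,0.229,1.453,0.242,1.807,0.352
5000,24,533,593,0.507,1.313,0.427,1.597,0.307
125x40,0,808,532,0.009,1,0,1.230,0.218
125x40,4,1427,605,0.016,1.623,0.219,1.955,0.208
125x40,24,450,483,0.628,1.800,0.324,1.883,0.341
500x10,0,639,897,0.047,1,0,1.223,0.279
500x10,4,1483,800,0.012,1.422,0.164,1.915,0.170
500x10,24,1067,844,0.090,1.577,0.155,1.767,0.261
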