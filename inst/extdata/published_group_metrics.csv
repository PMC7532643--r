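pulse,time_h,delta_ab_max_control_mean,delta_ab_max_control_sem,delta_ab_max_treated_mean,delta_ab_max_treated_sem,p_delta_ab_max,range_control_mean_um,range_control_sem_um,range_treated_mean_um,range_treated_sem_um,p_range
5000,0,-14612,5848,31889,6718,<0.001,77,5,149,10,<0.001
5000,4,1210,3502,3772,5138,0.684,107,7,101,6,0.519
5000,24,1522,425,-9509,7100,0.114,78,5,83,4,0.615
125x40,0,3101,3139,26031,6740,0.049,60,5,115,9,<0.001
125x40,4,615,4972,64647,24500,<0.001,74,5,107,11,0.002
125x40,24,-1902,1199,-1868,1217,0.984,87,6,80,6,0.423
500x10,0,27016,6422,64377,16119,<0.001,104,6,116,8,0.223
500x10,4,-4737,3501,19973,5713,0.028,87,6,78,7,0.403
500x10,24,1518,895,10284,3104,0.314,83,5,97,9,0.096
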