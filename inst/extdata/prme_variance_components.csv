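trait,pe_mean,u_mean,e_mean,h2,h2_sd,h2_hpd_lower,h2_hpd_upper
OH,542.23,367.04,1415.60,0.16,0.029,0.100,0.215
CH,276.32,138.89,784.17,0.12,0.025,0.067,0.165
Conv,631.57,487.25,944.30,0.24,0.047,0.147,0.329
Diver,593.19,308.43,853.16,0.18,0.048,0.086,0.270
CU,26.07,32.03,132.83,0.17,0.037,0.095,0.240
CO,461.32,584.53,1309.90,0.25,0.045,0.161,0.335
PTF,903.71,618.70,1046.00,0.24,0.046,0.152,0.332
SFF,636.58,374.52,755.11,0.21,0.051,0.117,0.311
BN,267.23,384.72,633.99,0.30,0.054,0.196,0.401
BW,270.58,315.13,584.43,0.27,0.048,0.175,0.363
BUF,457.33,477.58,1124.10,0.23,0.044,0.147,0.316
CF,294.29,240.99,692.73,0.20,0.040,0.118,0.274
Straight,342.65,288.71,940.42,0.18,0.038,0.110,0.258
Sloping,411.64,368.72,906.70,0.22,0.038,0.145,0.293
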