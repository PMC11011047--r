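trait,N,n0,n1,n2,pct0,pct1,pct2,pct12
OH,343,238,100,5,69.39,29.15,1.46,30.61
CH,483,181,233,69,37.47,48.24,14.29,62.53
Conv,412,252,122,38,61.17,29.61,9.22,38.83
Diver,432,251,148,33,58.10,34.26,7.64,41.90
CU,507,226,257,24,44.58,50.69,4.73,55.42
CO,356,341,15,0,95.79,4.21,0.00,4.21
PTF,318,178,126,14,55.97,39.62,4.40,44.02
SFF,439,144,255,40,32.80,58.09,9.11,67.20
BN,467,374,82,11,80.09,17.56,2.36,19.92
BW,476,363,108,5,76.26,22.69,1.05,23.74
BUF,418,311,98,9,74.40,23.44,2.15,25.59
CF,477,268,184,25,56.18,38.57,5.24,43.81
Straight,467,313,143,11,67.02,30.62,2.36,32.98
Sloping,452,310,137,5,68.58,30.31,1.11,31.42
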