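channel,nucleus.cytoplasm,nucleus.background,nucleus.unstained,cytoplasm.background,cytoplasm.unstained,background.unstained
R,0.06,8.27,2.38,3.86,1.06,3.31
G,0.85,15.89,6.27,4.21,1.02,2.38
B,1.17,5.74,0.04,1.00,1.03,4.44
H,1.76,1.10,11.19,1.26,73.13,1.09
S,0.02,0.96,0.03,0.7,0.08,1.31
V,1.25,14.48,3.75,2.17,0.15,2.85
L,0.68,7.67,3.30,2.52,0.57,3.05
a,0.87,2.09,4.74,0.18,1.54,1.97
b,0.14,0.45,4.38,1.28,6.70,4.89
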