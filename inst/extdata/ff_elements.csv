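element,lj_rmin_half,lj_epsilon,solv_radius,charge_fallback
C,1.908,0.086,1.70,0.00
N,1.824,0.170,1.55,0.00
O,1.661,0.210,1.52,0.00
S,2.000,0.250,1.80,0.00
H,0.600,0.0157,1.20,0.00
P,2.100,0.200,1.80,0.00
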