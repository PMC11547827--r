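complex,mutant,e_ele,e_vdw,g_pb,g_nonp
TNFa-TNFR1,,-33.51,-88.74,80.73,-9.28
aCC8-TNFR1,,-220.28,-39.82,230.90,-5.90
Mutant-TNFR1,L16R,-162.11,-45.50,174.56,-6.00
Mutant-TNFR1,L16H,-218.54,-40.05,231.22,-5.80
Mutant-TNFR1,L16K,-374.62,-43.31,388.43,-5.50
Mutant-TNFR1,L16D,-168.32,-34.33,181.74,-5.10
Mutant-TNFR1,L16E,-176.26,-36.65,191.16,-5.38
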