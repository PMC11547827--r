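source,region,serial,sequence,external_control
R1,Region 1,1,ASENHLRHCL,FALSE
R1,Region 1,2,FTASENH,FALSE
R1,Region 1,3,GSFTASENHLR,FALSE
R1,Region 1,4,ESGSFTASENHLRH,FALSE
R1,Region 2,5,CRKEMGQV,FALSE
R1,Region 2,6,SKCRKEMGQVEI,FALSE
R1,Region 2,7,SKCRKEMGQVEISS,FALSE
R1,Region 3,0,HYWSENLFQ,TRUE
R1,Region 3,0,YCWSQYLCY,TRUE
alpha,Region 1,8,TISRIAVSYQTKVNLLS,FALSE
alpha,Region 2,9,THVLLTN,FALSE
alpha,Region 2,10,THVLLTI,FALSE
alpha,Region 2,11,THVLLTNI,FALSE
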