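res_name,atom_name,charge
ALA,N,-0.40
ALA,CA,0.05
ALA,C,0.60
ALA,O,-0.55
ALA,CB,0.30
GLY,N,-0.40
GLY,CA,0.35
GLY,C,0.60
GLY,O,-0.55
VAL,N,-0.40
VAL,CA,0.05
VAL,C,0.60
VAL,O,-0.55
VAL,CB,0.30
VAL,CG1,0.00
VAL,CG2,0.00
LEU,N,-0.40
LEU,CA,0.05
LEU,C,0.60
LEU,O,-0.55
LEU,CB,0.30
LEU,CG,0.00
LEU,CD1,0.00
LEU,CD2,0.00
ILE,N,-0.40
ILE,CA,0.05
ILE,C,0.60
ILE,O,-0.55
ILE,CB,0.30
ILE,CG1,0.00
ILE,CG2,0.00
ILE,CD1,0.00
PRO,N,-0.40
PRO,CA,0.05
PRO,C,0.60
PRO,O,-0.55
PRO,CB,0.30
PRO,CG,0.00
PRO,CD,0.00
PHE,N,-0.40
PHE,CA,0.05
PHE,C,0.60
PHE,O,-0.55
PHE,CB,0.30
PHE,CG,0.00
PHE,CD1,0.00
PHE,CD2,0.00
PHE,CE1,0.00
PHE,CE2,0.00
PHE,CZ,0.00
TRP,N,-0.40
TRP,CA,0.05
TRP,C,0.60
TRP,O,-0.55
TRP,CB,0.30
TRP,CG,0.00
TRP,CD1,0.00
TRP,CD2,0.00
TRP,NE1,-0.30
TRP,CE2,0.30
TRP,CE3,0.00
TRP,CZ2,0.00
TRP,CZ3,0.00
TRP,CH2,0.00
MET,N,-0.40
MET,CA,0.05
MET,C,0.60
MET,O,-0.55
MET,CB,0.30
MET,CG,0.10
MET,SD,-0.20
MET,CE,0.10
SER,N,-0.40
SER,CA,0.05
SER,C,0.60
SER,O,-0.55
SER,CB,0.70
SER,OG,-0.40
THR,N,-0.40
THR,CA,0.05
THR,C,0.60
THR,O,-0.55
THR,CB,0.50
THR,OG1,-0.40
THR,CG2,0.20
CYS,N,-0.40
CYS,CA,0.05
CYS,C,0.60
CYS,O,-0.55
CYS,CB,0.50
CYS,SG,-0.20
TYR,N,-0.40
TYR,CA,0.05
TYR,C,0.60
TYR,O,-0.55
TYR,CB,0.40
TYR,CG,0.00
TYR,CD1,0.00
TYR,CD2,0.00
TYR,CE1,0.00
TYR,CE2,0.00
TYR,CZ,0.30
TYR,OH,-0.40
ASN,N,-0.40
ASN,CA,0.05
ASN,C,0.60
ASN,O,-0.55
ASN,CB,0.50
ASN,CG,0.80
ASN,OD1,-0.55
ASN,ND2,-0.45
GLN,N,-0.40
GLN,CA,0.05
GLN,C,0.60
GLN,O,-0.55
GLN,CB,0.50
GLN,CG,0.00
GLN,CD,0.80
GLN,OE1,-0.55
GLN,NE2,-0.45
ASP,N,-0.40
ASP,CA,0.05
ASP,C,0.60
ASP,O,-0.55
ASP,CB,0.10
ASP,CG,0.60
ASP,OD1,-0.70
ASP,OD2,-0.70
GLU,N,-0.40
GLU,CA,0.05
GLU,C,0.60
GLU,O,-0.55
GLU,CB,0.10
GLU,CG,0.00
GLU,CD,0.60
GLU,OE1,-0.70
GLU,OE2,-0.70
LYS,N,-0.40
LYS,CA,0.05
LYS,C,0.60
LYS,O,-0.55
LYS,CB,0.30
LYS,CG,0.00
LYS,CD,0.00
LYS,CE,0.30
LYS,NZ,0.70
ARG,N,-0.40
ARG,CA,0.05
ARG,C,0.60
ARG,O,-0.55
ARG,CB,0.30
ARG,CG,0.00
ARG,CD,0.10
ARG,NE,-0.30
ARG,CZ,0.80
ARG,NH1,0.20
ARG,NH2,0.20
HIS,N,-0.40
HIS,CA,0.05
HIS,C,0.60
HIS,O,-0.55
HIS,CB,0.60
HIS,CG,0.00
HIS,ND1,-0.30
HIS,CD2,0.00
HIS,CE1,0.30
HIS,NE2,-0.30
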