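# Small library of valid drug-like SMILES used by the synthetic-data
# generator (SMILES_FASTA mode). Synthetic fixture list, not a DrugBank
# extract.
CCO
CC(=O)O
CC(=O)Oc1ccccc1C(=O)O
Cn1cnc2c1c(=O)n(C)c(=O)n2C
c1ccccc1
C1=CC=CC=C1O
CC(C)Cc1ccc(cc1)C(C)C(=O)O
CC(=O)Nc1ccc(O)cc1
Clc1ccccc1
CCN(CC)CC
CCOC(=O)C
CC(C)O
CCCCCC
C1CCCCC1
c1ccncc1
c1ccc2ccccc2c1
CC(N)C(=O)O
NC(=O)c1ccccc1
OC(=O)c1ccccc1O
COc1ccccc1
CCOCC
CC(C)(C)O
CC#N
CCl
CBr
CO
CN
C=C
C#C
CC=O
OCC(O)CO
NCCc1ccc(O)c(O)c1
CN1CCC[C@H]1c1cccnc1
OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
CC(=O)OCC(=O)[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C
Nc1ccc(S(N)(=O)=O)cc1
CC1=CC(=O)c2ccccc2C1=O
OC(=O)CC(O)(CC(O)=O)C(O)=O
NC(N)=O
NC(=N)N
OC(=O)C=Cc1ccccc1
COc1cc2c(cc1OC)CC(N)C2
CN(C)CCOC(c1ccccc1)c1ccccc1
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
Clc1ccc(cc1)C(c1ccccc1)N1CCN(CCOCCO)CC1
OCCN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc32)CC1
CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1
CC(=O)SC1CC2=CC(=O)CCC2(C)C2CCC3(C)C(CCC3(C)O)C12
CN1CCN(CC1)C1=Nc2ccccc2Oc2ccc(Cl)cc12
OC(=O)c1cc(O)c(O)c(O)c1
COC(=O)c1ccccc1O
CC(C)CCCC(C)C
CCCCCCCCCCCCCCCC(=O)O
OCCO
OCC(N)=O
CSCC[C@H](N)C(O)=O
N[C@@H](Cc1ccccc1)C(O)=O
N[C@@H](Cc1c[nH]c2ccccc12)C(O)=O
N[C@@H](CO)C(O)=O
N[C@@H](CS)C(O)=O
OC(=O)CCC(=O)O
OC(=O)CCCCC(=O)O
C1CCNCC1
C1CCOC1
c1ccoc1
c1ccsc1
c1cc[nH]c1
c1cnc2[nH]ccc2c1
Cc1ccccc1
Cc1ccccc1C
Cc1ccc(C)cc1
CCc1ccccc1
COc1ccc(CCN)cc1
CN(C)c1ccc(cc1)C(=O)O
Oc1ccc(Cl)cc1
Oc1ccc(cc1)C(=O)O
Nc1ccccc1
Nc1ccc(cc1)C(=O)O
FC(F)(F)c1ccccc1
OC(c1ccccc1)c1ccccc1
O=C1CCCCC1
O=C1CCCN1
O=C(Nc1ccccc1)c1ccccc1
CC(=O)CC(=O)C
CC(=O)c1ccccc1
CCC(=O)O
CCCC(=O)O
CC(O)C(=O)O
OC(=O)C(=O)O
C(C(=O)O)C(=O)O
OCC1OC(CO)(OC2OC(CO)C(O)C(O)C2O)C(O)C1O
CN1CCCC1=O
O=S(=O)(N)c1ccc(N)cc1
CCOC(=O)c1ccccc1N
CC1CCC(C(C)C)C(O)C1
CC1=CCC(CC1)C(C)=C
c1ccc(cc1)c1ccccc1
O=Cc1ccccc1
OCc1ccccc1
N#Cc1ccccc1
O=[N+]([O-])c1ccccc1
CNC(=O)Oc1cccc2ccccc12
CCN(CC)C(=O)C1CN(C)C2Cc3c[nH]c4cccc(C2=C1)c34
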