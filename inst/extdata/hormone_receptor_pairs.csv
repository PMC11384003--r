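ligand,receptor1,receptor2
Ilp235,InR,
Crz,CrzR,
Dh44,Dh44-R1,Dh44-R2
Dh31,Dh31-R,
sNPF,sNPF-R,
Ms,MsR1,MsR2
ITP,Gyc76C,
Capa,CapaR,
Hug,PK2-R1,PK2-R2
Lk,Lkr,
Tk,TkR99D,TkR86C
Akh,AkhR,
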