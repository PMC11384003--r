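subtype,n_cells,criterion
l-NSC^DH31,6,ITP > 2 & Dh31 > 4 & amon > 0 & Phm > 0
l-NSC^CRZ,4,Crz > 3 & sNPF > 3 & Dh44 == 0 & ITP == 0 & ChAT == 0 & Gr64a == 0 & Phm > 0
l-NSC^ITP,7,Tk > 1 & sNPF > 1 & ITP > 1 & ImpL2 > 1 & Crz == 0
m-NSC^DH44,6,Dh44 > 2 & CG13248 > 0 & CG13743 > 0 & Lkr > 0 & Phm > 0
m-NSC^DILP,14,Ilp2 > 3 & Ilp3 > 3 & Ilp5 > 3 & ChAT == 0
m-NSC^DMS,5,Ms > 2 & EcR > 0 & rk > 0 & amon > 0 & Phm > 0
SEZ-NSC^CAPA,3,Capa > 0 & CrzR > 0 & trp > 0 & amon > 0 & Phm > 0
SEZ-NSC^Hugin,15,Hug > 3 & Dh44-R2 > 0 & amon > 0 & Phm > 0
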