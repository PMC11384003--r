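cell_type,category
V,aversive
DL4,aversive
DL5,aversive
DP1l,food
VA6,food
DL2d,food
VM7d,food
VA1d,pheromonal
VA1v,pheromonal
DA1,pheromonal
VL2a,egg-laying
DM1,food
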