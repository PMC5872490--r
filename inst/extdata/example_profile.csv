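cell_line,attribute,mu,sigma
HCT116,red,2100000,350000
HCT116,green,1500,210.75
HCT116,blue,3013000,640000
A2058,red,1800,120.5
A2058,green,2600000,84000
A2058,blue,3001000,910000
SW480,red,2050,310
SW480,green,1900,275
SW480,blue,3693000,720000
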