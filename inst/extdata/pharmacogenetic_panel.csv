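variant,genotype,count
rs1045642,AA,1
rs1045642,AB,5
rs1045642,BB,9
rs1751034,AA,1
rs1751034,AB,2
rs1751034,BB,12
rs757110,AA,3
rs757110,AB,8
rs757110,BB,4
rs2231142,AA,8
rs2231142,AB,6
rs2231142,BB,1
rs1042597,AA,3
rs1042597,AB,4
rs1042597,BB,8
rs1902023,AA,7
rs1902023,AB,6
rs1902023,BB,2
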