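((((Vpol,(Tpha,Tbla)n5)n4,((Ndai,Ncas)n7,((Knag,Kafr)n9,(Cgla,((Suva,Skud)n12,(Smik,Scer)n13)n11)n10)n8)n6)WGD,(Zrou,Tdel)n14)n2,((Klac,(Egos,Ecym)n16)n15,(Lklu,(Lthe,Lwal)n18)n17)n3)n1;
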