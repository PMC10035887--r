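((((((((Homo_sapiens:0.013,(Pan_troglodytes:0.0054,Pan_paniscus:0.0056):0.0084):0.0042,Gorilla_gorilla:0.0176):0.0166,Pongo_abelii:0.0344):0.0062,Nomascus_leucogenys:0.0422):0.0234,((((Macaca_mulatta:0.0082,Macaca_fascicularis:0.0086):0.0124,Papio_anubis:0.0198):0.0066,Chlorocebus_sabaeus:0.0262):0.0156,Rhinopithecus_roxellana:0.0378):0.041):0.0304,(Callithrix_jacchus:0.0602,(Saimiri_boliviensis:0.0522,Aotus_nancymaae:0.0474):0.0104):0.0696):0.0432,Carlito_syrichta:0.1224):0.0368,((Microcebus_murinus:0.0794,Propithecus_coquereli:0.0692):0.0302,Otolemur_garnettii:0.1098):0.0442);
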