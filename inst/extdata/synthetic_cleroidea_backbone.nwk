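((Byturus:0.25,Biphyllus:0.25):0.2,((Acanthocnemis:0.35,((Necrobia:0.15,Thanasimus:0.15):0.25,Phycosecis:0.4):0.1):0.1,((Rentonium:0.45,Phloiophilus:0.3):0.1,(((Peltis:0.2,Calitys:0.2):0.15,Thymalus:0.3):0.1,(((Eronyxa:0.2,Lophocateres:0.2):0.1,(Grynocharis:0.2,Ancyrona:0.25):0.1):0.1,(Trogossita:0.15,(Tenebroides:0.15,Temnoscheila:0.15):0.1):0.15):0.1):0.1):0.1):0.1);
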