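#NEXUS
BEGIN DATA;
  DIMENSIONS NTAX=19 NCHAR=93;
  FORMAT DATATYPE=STANDARD SYMBOLS="0 1" MISSING=? GAP=-;
  MATRIX
  Byturus        110001001000011101011100110100111100000101001011011011000010011110101110100000010001011011100
  Biphyllus      110011011000011011010001110001111000010001010001111001000011011100100101001100110101101001100
  Acanthocnemis  110111111001000000010010110110111110010010011010011000010110100000101100001001110101010101000
  Necrobia       101001011100011010011010110101100010011101011011010101101011001110111111010001100001001110000
  Thanasimus     110110011000011100000010110111001010011101011011000101001111011110111010000101100001101110000
  Phycosecis     111110011000001100011010110111101110111101010101110001101010111101111010010111000100001100000
  Rentonium      011011000001000111111110110111000000100000010101011001000011011100001001010000101111000010000
  Phloiophilus   110011000100011010010001110110011111001011001010010001000110011000011000010011011011010111100
  Foveapeltis    ?1????0?1??0011??00??00??1??0?10???1?01??101?0?1?0?0010??00?0????????????????????????????????
  Peltis         010111000001111000110010010010101111001101011000011000000100101101010101010011111100010110000
  Calitys        011010010101011001010010110010011111000111011001011001100110011101011000010011101101010110000
  Thymalus       110111001101011010000011110010100110100101011001111010001010001101001111011001110101100011000
  Eronyxa        001001111111111111000010110011011111100001111010011100101111011100001010011010000111001110000
  Lophocateres   000000111010111111010010110011101101100100010000011110100000011110000011011011011111001010011
  Grynocharis    110011001010001111110110010111001010100110010001010010000110011100001001010111001111000000100
  Ancyrona       010111001011011111010100100011001010100100001001011010000110010110001011110111000111010000001
  Trogossita     011010010011111101010100110111000111001100101000100000000001111110111010010011101101010010000
  Tenebroides    010011011010111100010111110110001111001100011000100110000000100111110001000011111100001011100
  Temnoscheila   010011011011111100010111110111000110101100111000110010000000001110000001010011011000111011001
  ;
END;
BEGIN SETS;
  CHARSET adult = 1-61;
  CHARSET larval = 62-93;
END;
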