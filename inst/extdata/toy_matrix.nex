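#NEXUS
BEGIN DATA;
  DIMENSIONS NTAX=9 NCHAR=30;
  FORMAT DATATYPE=STANDARD SYMBOLS="0 1" MISSING=? GAP=-;
  MATRIX
  Alpha     111111111111111000000000000000
  Bravo     111111111111111000000000000000
  Charlie   000001111111111000000000011111
  Delta     000000000011111000000000000000
  Echo      000000000000000111111111100000
  Foxtrot   000000000000000111111111100000
  Golf      000000000000000000001111100000
  Hotel     000000000000000000000000000000
  Fossilis  000001111111111000000000011111
  ;
END;
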