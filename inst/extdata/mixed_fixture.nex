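#NEXUS
BEGIN CHARACTERS;
  DIMENSIONS NTAX=9 NCHAR=85;
  FORMAT DATATYPE=MIXED(DNA:1-60,STANDARD:61-80,RESTRICTION:81-85) MISSING=? GAP=- SYMBOLS="012";
  MATRIX
    t1  CTGCACAACGCGACTTCCCA?GAACCTCAGGCTCGTACTCATTA?AACAGGAGTAATACA?20?0111?1110000011010110
    t2  CTG??CCACGTGA?TYA?CAAGATCCTCAAGCACGTGTCTGATAAGACAGG?ATCGTACA0210111110100010001010110
    t3  TTGCACCACGAGGCTTCCTAAGATCCTCACTCACGTGTTGAATAAGT?AGGCCTTGTGCG11?01001111100(01)1001110111
    t4  T?GCGCTGCGGACCTTTCTACGACCCTCAGGCATGTG?TCAATAAAACAGGGGTCATAAA01000112?1110?01011010010
    t5  TTGCGCTACGTATCTTCC?AAGATTCTCACTCACGTGTTGAATAAG?CAKGACTTGTGCA111011111111000000111?111
    t6  C?GCCCCACGTACCCTTCTAA??GCCTCAGACCCGTGTTTACTGAGACAGGAATTATGCA020001(01)11010000?001210110
    t7  ATGCGCTACGGAC?TTC?T?CGACTCTCA?GCYTG?GGTSAATAAAACAGGGGTCATACA020001021111?000011010010
    t8  CTG?ACTASGTACCTTCC?AAGWC?CTC?GGCACGTGTGTAATAAGGCAGGAC?CATACC1201011110110000001010010
    t9  CTGCTCCACAAGACCTACCAAGATCCTYGAGCCCGTGCCTAATA?AGCAGGGATCGTACG12001111100100101?0010110
  ;
END;
BEGIN SETS;
  CHARSET GHR = 1-60;
  CHARSET morphology = 61-80;
  CHARSET indels = 81-85;
END;
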