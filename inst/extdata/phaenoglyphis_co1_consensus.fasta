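>P_belizini
AATTTTATATTTTATTTTTGGAATTTGGTCAGGAATAATTGGATCTGCTTTAAGAATAATTATTCGTATAGAATTAGGAA
CTCCATCACAACTTATTGGAAATGATCAAATTTATAATTCAATTGTTACAGCTCATGCTTTTATTATAATTTTTTTTATA
GTAATACCTATTATAGTTGGAGGATTTGGAAATTATTTAGTTCCTTTAATATTATCAGCTCCAGATATAGCATTTCCTCG
TCTTAATAATATAAGATATTGATTATTATTACCAGCTTTAATTTTATTAGTATCAAGAATATTTATTGATCAAGGAGCAG
GAACAGGGTGAACAGTCTATCCTCCTTTATCTTCAAATTTAAGACATTCAGGAATTTCTGTTGATTTAACAATTTTTGCT
TTACATTTAAGAGGAGTTTCTTCAATTTTAGGAGCTATTAATTTTATTACAACAATTTTAAATATACGAGTAATTTCAAT
AGATAAAATTTCTTTATTTATTTGATCAATTTTTTTAACAACTATTTTATTATTATTATCTTTACCAGTTTTAGCTGGAG
GTATTACAATATTATTATTTGATCGTAATATAAATACTTCATTTTTTGATCCAATAGGAGGAGGGGATCCAATTCTTTAC
CAACATTTATTT
>P_evenhuisi
TTTATTATATTTTATTTTTGGAATTTGGTCAGGTATAATTGGATCCGCCCTAAGAATAATTATTCGTATAGAATTAGGGA
CCCCTTCTTCATTAATTGGAAATGATCAAATTTATAATTCAATTGTAACAGCCCACGCTTTTATCATAATTTTTTTTATA
GTAATACCTATCATAGTCGGGGGATTTGGTAATTATTTAGTCCCATTAATATTAAGGGCCCCAGATATAGCTTTCCCACG
TTTAAATAACATAAGTTTTTGATTATTGCCCCCTGCTTTATTTTTATTAGTTTCTAGAATATTTATTGATCAAGGGGCTG
GAACTGGATGAACGGTTTATCCGCCCCTTTCATCTAATTTAGGACATTCAGGAATCTCAGTAGATTTAACTATTTTTTCT
TTACATTTAAGAGGTATTTCTTCAATTTTAGGTGCAATTAATTTTATTTCAACAATTTTAAATATACGAATTATTTCCTT
AGATAAAATTTCCTTATTTATTTGATCTATTTTTTTAACAACTATTTTATTATTATTATCATTACCTGTATTAGCCGGAG
GAATTACAATATTATTATTTGACCGAAATTTAAATACCTCTTTTTTTGACCCTATAGGAGGAGGTGATCCAATTTTATAC
CAACATTTATTT
>P_longicornis
TTTATTGTATTTTATTTTTGGAATTTGATCGGGTATAATCGGGTCAGCTTTAAGAATAATTATCCGAATAGAATTAGGAA
CCCCATCTTCATTAATCGGTAATGATCAAATTTATAATTCAATTGTTACAGCTCATGCTTTTATTATAATTTTTTTTATA
GTCATACCAATTATAGTAGGGGGATTTGGAAATTATTTAGTTCCTCTAATATTAAGTGCTCCTGATATAGCTTTCCCACG
ATTAAATAACATAAGTTTTTGATTATTACCTCCTGCTTTATTTCTATTAATTTCTAGAATATTTATTGATCAAGGGGCTG
GAACTGGATGAACTGTTTATCCTCCTCTTTCATCTAATATAGGCCATTCAGGAATTTCAGTAGATTTAACTATTTTTTCT
TTACATTTAAGGGGAATTTCTTCTATTTTAGGGGCTATTAATTTTATTTCAACAATTTTAAATATACGAATTATTTCTTT
AGATAAAATTTCTTTATTTATTTGATCTATTTTTTTAACAACTATTTTATTATTATTATCATTACCTGTATTAGCAGGAG
GAATTACTATATTATTATTTGATCGAAATTTAAATACTTCTTTTTTTGATCCAATGGGAGGGGGAGACCCTATTTTATAT
CAACATTTATTT
>P_salicis
TTTATTGTATTTTATTTTTGGAATTTGATCAGGAATAATTGGATCAGCTTTAAGAATAATTATTCGAATAGAATTAGGCA
CCCCATCTTCATTAATTGGTAATGACCAAATTTATAATTCAATTGTTACAGCTCATGCTTTTATTATAATTTTTTTTATA
GTTATACCAATTATAGTAGGAGGATTCGGTAATTATTTAGTTCCTTTAATATTAAGGGCTCCTGATATAGCTTTCCCACG
ATTAAACAATATAAGTTTTTGATTATTACCCCCCGCTTTATTTTTATTAACTTCTAGAATATTTATTGATCAAGGAGCTG
GAACTGGATGAACTGTTTAYCCACCTCTCTCCTCTAATTTAGGCCATTCAGGGATTTCAGTAGATTTAACTATTTTTTCT
TTACATTTAAGGGGAATTTCTTCTATTTTAGGAGCTATTAATTTTATTTCAACAATTTTAAATATACGAATTATTTCTTT
AGATAAAATTTCTTTATTTATCTGATCTATTTTTTTAACAACTATTTTATTATTATTATCATTACCTGTATTAGCAGGAG
GGATCACTATATTATTATTTGATCGAAATTTAAATACTTCTTTTTTTGATCCAATGGGAGGAGGAGACCCTATTTTATAC
CAACATTTATTT
>P_stricta
GATATTATATTTTATTTTTGGTGTGTGATCTGGAATAATTGGGTCATCTTTAAGATTAATTATTCGAATAGAATTAGGAA
CACCAAACCAATTAATCGGAAATGATCAAATTTATAATTCTATTGTTACTGCYCATGCTTTTATTATAATTTTTTTTATA
GTTATACCTATTATAGTAGGAGGGTTTGGTAATTATTTAATTCCTTTAATATTATCCGCCCCCGATATAGCTTTCCCTCG
TTTAAATAATATAAGATTTTGACTTTTACCTCCTGCTTTATTATTATTAACATCTAGAATATTTATTGATCAAGGGGCTG
GAACAGGGTGAACAGTGTATCCTCCTTTATCATCTAATTTAGGTCATTCAGGYATTGCAGTTGATTTAACAATTTTTTCT
TTACATATAAGAGGAATTTCATCAATTTTAGGGTCAATTAATTTTATTACAACAATCTTAAATATACGAATTGTTTCAYT
AGATAAAATTTCTTTATTTATTTGATCCATTTTTTTAACAACAATTTTATTGTTATTATCTTTACCAGTATTAGCTGGAG
GTATTACTATATTACTTTTTGATCGAAATTTAAATACYTCTTTTTTTGACCCTATAGGAGGAGGRGATCCTATTTTATAY
CAACATTTATTT
>P_villosa
AATTTTATATTTTATTTTTGGAATTTGGTCAGGAATAATTGGCTCTGCATTAAGAATAATTATTCGTATAGAATTAGGGA
CTCCTTCACAATTTATTGGGAATGATCAAATTTATAATTCAATTGTGACAGCTCATGCTTTTATTATAATTTTTTTTATA
GTGATACCTATTATAGTTGGAGGATTTGGTAATTATTTAGTCCCTTTAATATTATCAGCACCAGATATAGCGTTCCCTCG
TCTTAATAATATAAGATACTGATTATTATTACCAGCATTAATTTTATTAGTTTCAAGAATATTTATTGATCAAGGGGCAG
GAACAGGATGAACAGTTTATCCACCTTTATCTTCTAATTTAAGACATTCAGGAATTTCAGTTGATTTAACAATTTTTGCT
TTACATTTAAGGGGGGTTTCTTCAATTTTAGGGTCAATTAATTTTATTACTACAATTTTAAATATACGAATTATTTCAAT
AGATAAAATTTCTTTATTTATTTGGTCTATTTTCCTAACAACAATTTTATTATTATTATCTTTACCGGTTCTAGCTGGAG
GAATTACAATATTATTATTTGATCGTAATATAAATACTTCTTTTTTTGACCCTATAGGAGGAGGGGATCCAATTTTATAC
CAACATTTATTT
>P_xanthochroa
GATTTTATATTTTATTTTTGGGATTTGGTCAGGAATAATTGGCTCAGCTTTAAGAATAATTATTCGAATAGAATTAGGAA
CCCCTTCTCAATTGATTGGTAATGATCAAATTTATAATTCAATTGTAACAGCTCATGCTTTTATTATAATTTTTTTTATA
GTTATACCAATTATAGTAGGTGGGTTTGGGAATTATTTAATTCCTTTAATATTATCAGCCCCTGATATAGCTTTCCCACG
TTTAAATAATATAAGATTTTGGTTATTAATCCCAGCTTTATTTCTATTAATTATAAGAATATTTATTGATCAAGGGGCAG
GGACTGGATGAACTGTTTACCCTCCTTTATCTTCAAATTTAGGTCATTCTGGGATTTCTGTTGATTTAACAATTTTTTCA
CTTCATTTAAGAGGAGTATCTTCAATTTTAGGGGCAATTAATTTTATTTCAACAATTTTAAATATACGAATTATTARAAT
AGATAAAATTTCATTATTTATTTGATCAATTTTTTTAACAACAATTTTATTATTATTGTCTTTACCTGTTTTAGCTGGAG
GTATTACTATATTATTATTTGATCGAAATTTAAATACTTCTTTTTTTGACCCTATAGGAGGAGGAGACCCAATTTTATAC
CAACATTTATTT
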