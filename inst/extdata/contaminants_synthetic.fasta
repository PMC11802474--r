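>uv_synth_vec001.1 Synthetic cloning-vector segment 1 (generated fixture, not a real UniVec entry)
AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGCAGCAATCTTG
CATCATTGTTATCGAACGGAGCCGGTATGAAGTACAGGACGTTGGGCAAGATACCATGGCAAGTGCCTGG
CGAAGGACGTTAAGTTTGAGGAAAGCACAAACGTACCATCCAAGGACTGG
>uv_synth_vec002.1 Synthetic cloning-vector segment 2 (generated fixture, not a real UniVec entry)
TGCTTGCGTGAACCTAACCATTTTTCCGACGACTTGGTCGATTTAGTTACAGTCGTGATCGGCCTTGAAA
ATCCCGAATAGTATACCGATACGGCACCTAGGCTCCAAGCGATAGCTACAGAGCAAGGCTCAACGCCATG
GATATCGGCGCCAATCCACAGATGATGACCTGACGTACTCCCGATTCCAAGCACCGGCCT
>uv_synth_vec003.1 Synthetic cloning-vector segment 3 (generated fixture, not a real UniVec entry)
CCTTCGTTTCTCCGTGGTCATGCGCTATACGCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATT
CGATCTCCTAGTAAGGATTGTCCCTCCATGCTATGTGTCTATGTTCGAGGCTGCTTTCGTTATTACTTGA
AGTTAGTATGAGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCGTCTGTGGTTACGCCAA
>uv_synth_vec004.1 Synthetic cloning-vector segment 4 (generated fixture, not a real UniVec entry)
CTTCAGTAACACCGTTAACCTGTAGAGCGGATTTAGACTGTGGGGTTGAAAGTAAACGCCTTAGCCCAAG
TTTGCAGAACACGTCCACATCCCTTTAACTTGCTTCAGCGCAACTCAGTCATTTGTAATTCCCGCCAAAA
TGAATGATTACGCAGCGAGTACATCTGCCGCTTATAGAAAGTGGGCGCTGGACCTATGGGCCTGAATAGG
TACAACCGGT
>uv_synth_vec005.1 Synthetic cloning-vector segment 5 (generated fixture, not a real UniVec entry)
AGCCCTGACGGTGAACTGCTGGATGGATGGTTCTTATGCGAGAACGGCGGTCGCGCCACGGTCTACATAA
GGTTCTTGCACTGTTTAATTCAGACCTACGACTCTGCCTGCAAATAAATGTTGAGAAATACGAGTATAAC
TCAAGAGATGTCGTCATGTTGCTGCAAGATCAGCGATCGCGGTACCGGCTTAGTAAACTTTGCCAAAACG
CGTGTTCTGCCTACAGGGCG
>uv_synth_vec006.1 Synthetic cloning-vector segment 6 (generated fixture, not a real UniVec entry)
AGGTAGGAAAGTGGAAGCTCTGAAATGAACTCTATTGTTCGAAGTTGGGTTAACAGGTCGGAAAATTAGT
GACGTCAATTTACCCGATGGGCCGACTATCATGTTCGGACAAGCGGGTAACGATCCGGTCTCTTCAAGTC
CCCCTACTACCAGTAACTGACGCCCTTCCGAATTTAGTGCTGTCTAGTCAATTCGTACTTGTTACATATT
TGAGAGCCCTTTGATTCACATTAGAATACA
>uv_synth_vec007.1 Synthetic cloning-vector segment 7 (generated fixture, not a real UniVec entry)
GACCGCCGAACATTTTAAGAGTACCAGTCGGGCGATCCTCGACGGAGCAACGCAGAGATTAGCAGGCAGC
TCGACCGCCCTTACTGTAGCGACTGGTTTGACCTTCCTAGACCGGTGGCGCTAGACTCGTACACTCAGGA
TTTTAACTATACGCACGCGCCGTCTTGATGACGCCCGATTGCCGTTGCAAGGTGCCTACCCACGGTTGGG
TTCCGCGTGCCACGCTACAACAGACACGGGCTCAGTATGC
>uv_synth_vec008.1 Synthetic cloning-vector segment 8 (generated fixture, not a real UniVec entry)
ACCGACTAACATAGCCCTCCTTTCTTGACGCAATTGTGTCACATTATGTCCGGCGGCAGAGGCGAAGCTG
TCCAGATATCCTAGTATGAGATAGCCTGATTGAATAGTTTTTAGGCGCCGTGATATCAAGGTTAAGATTT
TGTACTAGCCAGATAGGATTTACAGAACAGGGGGCATACGAATTGAGATTGCATCTTGTGACGATGCGTA
CTCCTCCATGCAGACGTATGCTAGCACCTTCTCATTCGAGTCTAGTTGGC
>uv_synth_vec009.1 Synthetic cloning-vector segment 9 (generated fixture, not a real UniVec entry)
GCTTCGCATACCATAGTCTTGCTAGTCGGGGTTGTTACCGCTGTACATCAAAACGTGTTTTGCAGTATAG
TTACTTCGAACTTCTCAAAAAAGAAACCAAAGGACCTCAATGAGAGCTCTAACCCCTACTTGTGGTGAGA
CAAGGTTAGTAATCCGGGGAGCTACATAGGATCGTGTAACATTGGACGACAACCTCTAGGACGGAGGGCG
TTGGGCCAGCCATAAGTCCAGCTCAATAGAGTTACAAGATGTTATTGGCCTCACTGAGCG
>uv_synth_vec010.1 Synthetic cloning-vector segment 10 (generated fixture, not a real UniVec entry)
TTAATGGATGCGCAAACGTGACAGGAGGGGCAATCAGATGCGGGGTAGAAACCTAGAAGGTATATCCCTA
TAGATACCCGTAGAATGAAATTCGCGGGGGTCAAGCAGGGAACGTCCAGAAAAACTAGTTGAGCAAGATA
CCGGAGGAGATTAATGTACGGAGACTGCGATCCTGTGCCCATCTAACACGAAGGCCGTGACTACGGGCCA
TGAAGGGAAATTTACCCTAGGAAGTGTTCTGAAATCGCGCATGGTACGAGTATGGGGCGGACCCCAGGAA
>uv_synth_vec011.1 Synthetic cloning-vector segment 11 (generated fixture, not a real UniVec entry)
GCGGCCACCGGAGCGCGCTGGGCAGTGATAGACTCTCATAATATGGATCGAGCTACATCAATACTAACGG
AAATTATGATTGCAGACCCGTATTAAAGATTACTTATGACTTATTCGCATAGGTGAGGTCGAGTACTCAC
AGGCGATACCCGCCGACCTCTTTCTCGTCATAACGCGGGCCAAATTCTACCAGGATCTAAGGCAAACAAC
TCCCGGGACCCGCTGAGACGCACTAGCCCCGACGTGAGGAAACCGCGACGGCGGGTGGAAACGGGGGATA
GTGTCGCGGC
>uv_synth_vec012.1 Synthetic cloning-vector segment 12 (generated fixture, not a real UniVec entry)
GCTCGTGAGGTAATGAGCCCGGGTCCAATCCGATACCAATGCTGTCTAATACCAGAGAGGAACAACTTCC
TTCGAGGACGGCTACGCTCGGCTCCATTCCATGGGTATTCAGTTGATGGGGGGTAAGTAACGTCCCGGGT
CTTCACAGAACAAATTAGCGGTGTTTTCGGGATGCCCCGGTAGGGGGGTAGATGACTAGCCTTAGCTCGG
CGTTCTCTGGTGCAATGAACAAGACGCTTAGATCCGTCTAGTACCCGCACCCGCCCGAACACAAATGGTT
GAGAGGCTTAGACCCGTCAG
>uv_synth_vec013.1 Synthetic cloning-vector segment 13 (generated fixture, not a real UniVec entry)
CTTACCAGTAACAGGATCTGATAGGGCTTAGGCGGATGCAAGGCCTCTAGCTTTCGAGGATTTGAAGGCA
CTCGATGCAGGTAAGGTATCAGACGATCCGAGTCAGATGGAGCAACCTGAAGGCGGCGGTTATTCCCCAT
ATTCACTTATTAGCGGAAATGCGGGCGCACAACCTACCCATCCAAATCAGGCAGCCTCGGTTTGCCATAG
TCCTGGGTAGAGAGATAGCCCCATTTGATCTCCTAGGCTAATCCCGGTATGCATTCCCCCTATAGTTCGT
CGAACATCGAGCTAATGAAGGGACGCATTG
>uv_synth_vec014.1 Synthetic cloning-vector segment 14 (generated fixture, not a real UniVec entry)
GGTACGACACACTTATAATAAATGGTTCACTTCAACACACTGATGCATAATGTACCAATCTGCCAGGCCC
GCTAGCCGTTGTCAACCAAAAGAATCTCGAATGGACAAGGTATATGGTGCGCGCTCTGCGAACAGGTGAC
CGTTTAGGGCCACCATCTAAGGTCAGTGCCTGTCTACTGAACGTACGTAGTCCGTCGGGGACCCTCCCCC
GAATCGAGTGCTTGCACTTAGTGTCTCAACGTACGAGGGTCGACAAGCCCTCCTATCCCTTATTGGAAAG
TGGAAGTTTCATCGCATGAATTAACTTGAGAGTAAGTCAT
>adp_illumina_truseq_r1 Illumina TruSeq adapter, read 1
AGATCGGAAGAGCACACGTCTGAACTCCAGTCA
>adp_illumina_truseq_r2 Illumina TruSeq adapter, read 2
AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT
>adp_illumina_nextera Illumina Nextera transposase sequence
CTGTCTCTTATACACATCTCCGAGCCCACGAGAC
>adp_ont_ligation_top ONT ligation kit adapter, top strand
AATGTACTTCGTTCAGTTACGTATTGCT
>adp_ont_ligation_bottom ONT ligation kit adapter, bottom strand
GCAATACGTAACTGAACGAAGT
>adp_ont_rapid ONT rapid adapter
GTTTTCGCATTTATCGTGAAACGCTTTCGCGTTTTTCGTGCGCCGCTTCA
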