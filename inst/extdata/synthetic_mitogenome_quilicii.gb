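LOCUS       SYNQUIL1 1600 bp    DNA     circular INV
DEFINITION  synthetic annotated genome SYNQUIL1.
FEATURES             Location/Qualifiers
     source          1..1600
     tRNA            1066..1121
                     /product="tRNA-Ile"
     tRNA            1184..1252
                     /product="tRNA-Gln"
     tRNA            1271..1299
                     /product="tRNA-Met"
ORIGIN
        1 ttcaattctg attggccact aatataacat ggatttatta cacattacca aatagattca
       61 cttgtgtccc tgtcaaattt gcccatctta tacttgataa ttaccgatta gtatcgtaca
      121 tgctaattca ctaagtcact gttcaattga ggatctcaac taatcggtta ttaaaaaatt
      181 tagcagaact atttgtctta ccagaacccc caattcatac catttatgat cgtcaaatag
      241 atacctagat atagcagcaa ttattagtta tgtatcaatt ctgtctacta tattaaaatg
      301 attttatgta aaagtcgctt tgtcattgaa aatctttttg aatagttgat tttaataatt
      361 ttatttgata ttatgtcatt tatattcgat gtatttcgaa cttgtaaagc tattatcata
      421 atttagacga atttaatcaa aattctagta taagcaaatt agactatacc aatatggaaa
      481 atttagtgta ttatagttta agtggatgct taattaagaa cttatgtttt tgtatagtgt
      541 ataaacccgt gttaaactaa gttttaacat aaataaaaat aaaatgtgtt tacggtatat
      601 acttaaaatt aagctggctc ttaatgtttt cattcaacta ataagattta tgttacagct
      661 tttcagcttc gaatattttt attaggtaga ctgcagtcac taaacatgct atagttttat
      721 cattatagca tcttcaaaca tagttcattg tattttgaca ggttaaataa ttaatctgtt
      781 acttatttat tgtgggtgtt tattcatact acaaaacaat aaatgagctg acattatgcg
      841 tgagggttac atcataattc tacaaatatt tacaataagc taatgcatca ccaattctct
      901 tccctatcca tatagttatt ttagttaaat acgattagtc taaatagcat tctttgtatt
      961 ttaagaaata gtaataataa tagtttaatt tcataaataa attgtcgcat tacttgtaac
     1021 aattattcga atgtaagaaa tatcgttcgc tcaaaaagat ttagttgaca aaagggttac
     1081 cttgataggg atttaggtta aaccatttga cttgcaatca atactatgta ttataatttg
     1141 ttcctccgat tagatatcat aaacttttgc aagttcaaac tcgtattcaa caaatcattt
     1201 agggtataaa tcctaataat tttacaatta acctttgaaa gttaaagttt acttcatcat
     1261 tatcttactg attaagataa gctaattaag ctactgggtc aatgtcttaa ttcatagtta
     1321 tttatagaca tataggattc ttttatacaa tacattttaa actatcttgg ttagtagtaa
     1381 aacacttcaa aaatcgacct tgtaaaggta taattgatac tctggccaca ttatctataa
     1441 taatttgtat attacctttc aacattacta ctatatgtat atatatcaat tatcataata
     1501 ctaattccaa attaatcact cattatattc taataatcta tttgaaaaaa aaataaataa
     1561 cgtactattt gtgtttgatt atatttgata tatatatgta
//
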