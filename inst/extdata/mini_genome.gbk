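LOCUS       MINIGENOME        600 bp    DNA     linear   BCT 01-JAN-2026
DEFINITION  synthetic bacterial chromosome MINIGENOME.
ACCESSION   MINIGENOME
FEATURES             Location/Qualifiers
     source          1..600
     CDS             10..60
                     /locus_tag="MINI_0001"
                     /product="hypothetical protein"
                     /translation="MRVKTVQFYAPALERSS"
     CDS             complement(101..160)
                     /locus_tag="MINI_0002"
                     /product="phage integrase"
                     /translation="TWARTFAPQHLPQNLRDSPR"
     tRNA            301..375
                     /locus_tag="MINI_0003"
                     /product="tRNA-Leu"
ORIGIN
        1 gagctcgtta ttagggtaaa aacggtacaa ttttatgcgc ctgctcttga gcgctcatct
       61 ctggtcgcac agtttatagg ggagtaatac acataactta acgaggtgaa tctcgtaaat
      121 tctgtggcaa atgctgtggg gcgaaggtac gagcccatgt tggtacccca ggtacataga
      181 tagtccccac tgtggggcgc agttagagaa ttcgtattgg tccataatag cgagatttac
      241 gggtagagtc catgcaccat gctacaccta tccgggagta gacgggcctt actcggaacg
      301 actactcaga aattgtcgcc tcaccataaa aggcgacaac ccatgtgtac ggagcagggg
      361 agattcataa actgcctaca gacgacagac aggtaggctg agtaaagtaa aatcaataaa
      421 tcatcagtag acatctactt acccttctct ggtattgtta agtccgctag agtgggtgca
      481 caagggttat ataactccgt tgttaagtct caaacttaga agtcccaaag gggcaatcac
      541 accgacaaaa cctaaaaacc gtcgttgcgt gtcccatccc tgcaaagaac agcctccacc
//
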