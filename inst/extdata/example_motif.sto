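# STOCKHOLM 1.0

#=GS seq1 GENE PRK07324
#=GS seq2 GENE PRK07324
#=GS seq3 GENE GNAT
#=GS seq4 GENE PRK07324
#=GS seq5 GENE MATE
#=GS seq1 PHYLUM Firmicutes
#=GS seq2 PHYLUM Bacteroidetes
#=GS seq3 PHYLUM Firmicutes
#=GS seq4 PHYLUM Actinobacteria
#=GS seq5 PHYLUM Firmicutes
#=GS seq1 ENV gut
#=GS seq2 ENV gut
#=GS seq3 ENV non_gut
#=GS seq4 ENV gut
#=GS seq5 ENV unknown

seq1         GGCGCAAGGUUCAACCAGCGCCAUCGGGCUUAGCCC
seq2         GGCGCCAGGUUCAACCGGCGCCAUCGGGCAAAGCCC
seq3         GGCACAAGGUUCAACCUGUGCCAUCGGGC-UAGCCC
seq4         GGCGCAAGGUUCAGCCAGCGCCAUCGGGCUU-GCCC
seq5         GGUGCAAGGUUCAACCAGCACCAUCGGGCUUAGCCC
#=GC SS_cons <<<<<..AAAA....>>>>>...aaaa<<<...>>>
//
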