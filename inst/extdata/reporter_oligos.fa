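>wildtype_insert sense strand of the CLTC 3'-UTR reporter insert (XhoI/NotI cloning ends)
TCGAGAGACAACTTGCCTGATTTTTAAATGAGCGTAAAAGGCCCTGC
>mutant_insert sense strand with the seed-complementary heptamer replaced by TTTTTTT
TCGAGAGACAACTTGCCTGATTTTTAAATTTTTTTAAAAGGCCCTGC
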