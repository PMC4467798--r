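>1Fmut forward 98..144 engineered G at 3'-offset 2
ATGCCTTCGTTTTCTTGGTGAATTTTTGGGATGTAGTGAAGAGGCGG
>1R reverse 274..300 perfect match
CATCCATAGCATGATGATGGCTTGGTA
>2Fmut forward 739..784 engineered A and C at 3'-offsets 4 and 2
AAGTCTCTTGTCTCCTTTTTCTGCTTCTTTGTGATATCATCCAGCG
>2Rmut reverse 887..932 engineered base at 3'-offset 2
ATGGTCATCACAGCTCTCCTCAACTTGGCATTGCCTGAGATCAGTA
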