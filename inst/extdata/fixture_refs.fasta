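>NM_006766.3 KAT6A mRNA, reconstructed window 3686-3764
GATGTACTCAGGTGTCAGTCCTCTTCTAAGAGGAAGTCTAAAGATGAAGAAGAAGATGAAGAGTCAGATGATGCTGATG
>NM_004380.2 CREBBP mRNA, reconstructed window 212-380
AGAACTTGCTGGACGGACCGCCCAACCCCAAAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGCCTTTTAAACAGTGGGAACCT
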