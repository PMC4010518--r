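>read_01
CCCAAAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGAT
>read_02
CGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGCCTTTTAAACAGT
>read_03
AAGAAGAAGATGAAGAGTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTA
>read_04
ACTTGCTGGACGGACCGCCCAACCCCAAAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAA
>read_05
ATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAAGATCGGAAGAGCGTCGTGTAGGG
>read_06
GTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGCCTTTTAAACAGTG
>read_07
AAGAGTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGCCTTTTAAAC
>read_08
AGAGTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGCCTTTTAAACA
>read_09
AGAACTTGCTGGACGGACCGCCCAACCCCAAAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTG
>read_10
GACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGCCTTTTAAACAGTGGGAACCT
>read_11
AACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGTAGGA
>read_12
CTGGACGGACCGCCCAACCCCAAAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGA
>read_13
AGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCAGATC
>read_14
GAAGATGAAGAGTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGGCAGATCGGAAG
>read_15
GCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGG
>read_16
CTCAGGTGTCAGTCCTCTTCTAAGAGGAAGTCTAAAGATGAAGAAGAAGATGAAGAGTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAA
>read_17
CTTGCTGGACGGACCGCCCAACCCCAAAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAA
>read_18
AAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCC
>read_19
CAGTCCTCTTCTAAGAGGAAGTCTAAAGATGAAGAAGAAGATGAAGAGTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCC
>read_20
GCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGG
>read_21
AAAAGAGCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACC
>read_22
GCCAAACTCAGCTCGCCCGGTTTCTCGGCGAATGACAGCACAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAGATC
>read_23
GATGTACTCAGGTGTCAGTCCTCTTCTAAGAGGAAGTCTAAAGATGAAGAAGAAGATGAAGAGTCAGATGATGCTGATGATTTTGGATCATTGTTTGACTT
>read_24
ATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGAGATCGGAAGAGCGTCGTG
>read_25
GTAAAGGTTGCTTAGTTTCTCATTTCCATTTCTGTTTAATTTCTAGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAA
>read_26
GATGATGCTGATGATTTTGGATCATTGTTTGACTTGGAAAATGATCTTCCTGATGAGCTGATACCCAATGGAGGAGAATTAGGCCTTTTAAACAGTGGGAA
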