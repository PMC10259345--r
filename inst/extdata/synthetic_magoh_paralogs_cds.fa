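>MAGOH_SYNTHETIC synthetic CDS stand-in (86% identity by construction)
ATGGAGTCGGATTTCTATTTGAGATATTATGTCGGACACAAAGGCAAATTCGGACATGAATTCCTTGAATTCGAGTTCCGGCCTGATGGCAAACTACGTTATGCCAACAACTCCAACTACAAGAATGATGTTATGATCCGTAAGGAAGCATACGTCCATAAAAGCGTAATGGAGGAGCTGAAGCGGATTATTGATGATTCAGAGATCACGAAGGAGGATGACGCATTGTGGCCTCCCCCAGATAGAGTTGGGAGGCAGGAGTTAGAGATAGTAATTGGTGATGAACATATTTCCTTCACTACTTCCAAAATCGGGTCGCTAATCGACGTTAATCAGTCGAAGGACCCTGAAGGGCTCCGAGTGTTCTATTACCTCGTTCAAGACCTTAAATGCCTAGTCTTCAGCTTGATCGGGCTACATTTCAAGATCAAGCCAATATAA
>MAGOHB_SYNTHETIC synthetic CDS stand-in (86% identity by construction)
GCGACTTCAGATTTCTATTTGAGATATTACGTCGGGCATAAAGGCAAATTTGGTCATGAGTTTCTTGAGTTTGAGTTCCGCCCTGACGGCAAACTACGTTATGCCAATAATTCCAACTATAAGAACGATGTGATGATCCGAAAGGAAGCATACGTCCATAAGAGCGTAATGGAGGAGCTGAAACGCATTATTGATGACTCAGAAATCACGAAAGAAGATGACGCACTGTGGCCACCCCCAGATCGAGTTGGGAGGCAGGAGTTAGAGATTGTTATAGGGGATGAGCACATTTCGTTTACTACTTCCAAAATTGGGTCGCTAATCGATGTAAATCAATCTAAGGATCCCGAGGGCCTGCGGGTATTCTACTACCTCGTTCAAGACCTTAAGTGCCTCGTCTTTAGCCTGATAGGGCTACATTTCAAAATAAAGCCTATATAA
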