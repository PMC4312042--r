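>hvr1_window_16024_16384 synthetic stand-in reference (not rCRS)
ACAAATGAACACAGTTCCCGACCCACTCTCCCGTAACCACTACGGGCTTAACAACTACAT
GTCTGATCTTATAACAACCTAGACGAAATCTCGGAAGTCGCAAGCGCCTCAGACCCCCTT
ACGCCTATTTCCTTAACCCACAACGGCCCTTGCCTAACAGCCGCATCGAACAGCGGACGC
TATTATACCCCCTCGGCCGCGAACCGCAATACGCCATTCACTTGTATAATATCTCCCCTC
TAACCTCGTATCCGAAAATCAATGTGAACCCTTACATAAATCGCTCATCACTCCCAGATT
GACCGACTATTTCCCAGCAATTGCCCTATGACACACCATATTACACAGTGCCTAAATAGT
A
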