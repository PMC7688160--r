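target,forward_primer,reverse_primer
Acta2,tctggacgtacaactggtattg,ggcagtagtcacgaaggaatag
Actb,caagcaggagtacgatgagtc,aacgcagctcagtaacagtc
Cdh11,acaccatgagaagggcaag,accggagtcaatgtcagaatg
Col1a1,cataaagggtcatcgtggct,ttgagtccgtctttgccag
Ccn2,ctccacccgagttaccaatg,gccctgtatgtcttcacactg
Gapdh,atgacaatgaatacggctacag,tctcttgctcagtgtccttg
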