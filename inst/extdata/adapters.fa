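>TruSeq_adapter_read1 Illumina TruSeq adapter, read 1
AGATCGGAAGAGCACACGTCTGAACTCCAGTCA
>TruSeq_adapter_read2 Illumina TruSeq adapter, read 2
AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT
>Illumina_smallRNA_3p Illumina small RNA 3' adapter
TGGAATTCTCGGGTGCCAAGG
>Illumina_smallRNA_5p Illumina small RNA 5' adapter
GTTCAGAGTTCTACAGTCCGACGATC
>Nextera_transposase Nextera transposase sequence
CTGTCTCTTATACACATCT
>Roche454_primerA Roche 454 Titanium primer A
CGTATCGCCTCCCTCGCGCCATCAG
>Roche454_primerB Roche 454 Titanium primer B
CTATGCGCCTTGCCAGCCCGCTCAG
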