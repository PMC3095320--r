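promoter,gene_id
GmERF1,Glyma20g16920.1
GmERF2,Glyma20g16910.1
GmERF3,Glyma11g03900.1
GmERF4,Glyma01g41530.1
GmERF5,Glyma05g05180.1
GmERF6,Glyma05g05130.1
GmERF7,Glyma19g43820.1
GmERF8,Glyma20g34570.1
GmERF9,Glyma10g33060.1
GmERF10,Glyma17g15460.1
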