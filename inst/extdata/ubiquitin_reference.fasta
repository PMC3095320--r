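>ubiquitin_monomer canonical 76-residue eukaryotic ubiquitin unit
MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYN
IQKESTLHLVLRLRGG
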