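Glyma01g22260.1
Glyma02g11060.1
Glyma05g07840.1
Glyma08g24110.1
Glyma11g05450.1
Glyma14g00600.1
Glyma15g25120.1
Glyma17g17010.1
Glyma18g01030.1
Glyma19g43260.1
Glyma19g43260.2
Glyma19g45390.1
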