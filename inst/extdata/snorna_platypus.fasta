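>snoRNA_platypus AAPN01359272.1/4977-5048 72 nt small nucleolar RNA, Ornithorhynchus anatinus
AGCACAAAUGAUGAGCCUAAAGGGACUUAAUACUGAAACCUGAUGUAACUAAAUAAUAUAUGCUGAUCGUGC
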