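>snoRNA_galago AQR01179445.1/1047-1115 69 nt small nucleolar RNA, Otolemur garnetti
GGCACAAAUGAUGAAUGACAAGGGACUUAAUACUGAAACCUGAUGUUACAUUACAAUGUGCUGAUGUGC
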