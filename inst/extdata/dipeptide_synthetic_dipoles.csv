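mode,mux,muy,muz
1,0.10,0.00,0.40
2,0.55,0.42,0.62
3,0.61,-0.35,0.58
4,0.42,0.12,0.05
5,-0.10,0.44,0.02
6,0.90,0.10,0.30
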