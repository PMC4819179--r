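0.7176038013 -0.6959778383 -0.0256833222
0.3896730414 0.8112703483 -0.435884552
0.204095851 -0.2181832486 0.9543274876
0.0014234955 0.7133473621 0.7008091856
-0.9593147556 -0.2462877259 -0.1380491067
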