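0.5335835699 0.7329077277 0.4220602287
0.3103853219 0.8045321938 -0.5063485965
0.5241425624 -0.6541813471 0.5452718032
-0.2828286347 0.460188845 0.8415665098
-0.9018058137 -0.09586981 -0.4213730579
-0.1542235418 0.1150156574 -0.9813187544
-0.1727224042 0.9698801127 0.1717542958
-0.813402486 -0.2676184289 0.5164850165
0.8609359489 -0.4586827932 -0.219998607
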