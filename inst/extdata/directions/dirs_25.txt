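0.8097100477 -0.5591371956 0.1781438606
0.8693940927 0.4354934072 -0.2334510738
0.7295526013 0.3009847538 0.6141344967
-0.6358822816 0.4015313896 0.6591102086
-0.9828814944 -0.122718689 -0.1374193998
0.4569807926 0.0896734653 -0.8849447581
-0.6242101788 0.7276569966 0.2843887269
-0.943221373 0.2645515491 0.200862937
0.8323680371 0.0739407264 -0.5492688046
-0.3313329066 -0.7065814783 -0.6252688379
0.7412247014 0.6271102836 0.2394131038
-0.2934074394 -0.2982616827 -0.9082687065
-0.8467360964 0.1975847038 -0.493961808
0.505213137 0.5378092775 -0.6749228603
0.1827355953 -0.7444359437 -0.6422015477
-0.0579186827 -0.9386367711 0.3400094676
-0.4958709187 0.1598395884 -0.8535592176
0.5304921605 0.8074988079 -0.2579219703
-0.1865229917 0.3336026734 0.9240770692
0.163865002 -0.9666805953 -0.196664404
-0.0234898079 -0.6563194324 0.7541173858
0.4641617319 -0.6091917615 0.642992445
0.316065436 0.9313397935 0.1808558245
0.4223595836 -0.8776640071 0.2265353676
-0.0168672789 0.2083642684 -0.9779058373
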