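0.7696056588 0.6385157739 0.0021763542
-0.0308347499 0.4678695944 -0.8832594527
0.8527906352 0.2174284408 0.474839979
-0.2997478615 0.0697450336 0.9514656325
-0.9142345232 -0.3831597968 0.1317717978
-0.3734900232 0.6090168662 -0.6997168422
0.0043231518 0.8535269776 0.5210307177
-0.9521324596 -0.1033097969 0.2876992619
0.8704069649 -0.4765593549 -0.1236240135
-0.728945554 -0.6044408331 0.3213870853
0.4280609758 0.4724184953 0.7704443954
-0.2538285513 -0.8990779651 -0.3566929762
-0.3383729023 0.8171086026 -0.4667304474
0.3952701612 0.2518599857 -0.8833617873
0.4735664125 -0.6066615268 -0.6385112723
0.4637901959 0.7157302096 0.5221387951
-0.3761579961 0.9184140331 0.1225594788
0.8200791493 0.0104748253 -0.5721542335
0.1911800856 0.6917336769 0.6963868861
0.5512124606 -0.8094140926 0.2025182706
0.6118086939 -0.3664037261 0.7010266982
0.6189861298 -0.6232440305 0.4779362401
-0.2763269095 0.9457374479 -0.1709506327
0.2872479084 -0.8422538821 -0.4561765417
-0.2005526817 0.1019144977 -0.9743675164
0.7755588311 -0.0749906152 0.6268053183
0.817465103 -0.3514189728 0.4563502065
0.9906731794 0.1189091922 0.0665376256
0.6768374299 -0.7323130284 -0.0748914005
0.1216798635 0.4500671147 0.8846658144
-0.1013969833 -0.1979421295 0.9749551606
0.7404533224 -0.5277930712 -0.4161290082
-0.5850585953 0.0414190735 0.8099326518
0.9021692812 0.3784217489 0.2070931384
-0.9377501743 0.3068167231 -0.1627516792
0.1624240167 -0.6608079204 -0.7327696304
-0.4837109482 -0.7561331784 0.4407792362
-0.3405306789 -0.1932538205 -0.9201585829
0.1820799639 -0.3984032315 -0.8989559232
0.5531543558 -0.7557279757 -0.3505645239
-0.5398767397 -0.8320849448 0.1271524697
-0.6772033469 -0.457167175 -0.5765360362
-0.2767897999 -0.9596861982 -0.0488856582
0.2662864304 0.5276924583 -0.8066177573
0.3241557401 -0.3626689657 0.8737243716
-0.8168978166 -0.346544151 0.461069527
-0.6321262409 -0.1920364208 -0.7506919665
-0.9417120573 0.0433102046 -0.3336204838
-0.0328089604 0.9053863669 -0.4233191453
-0.8955310868 0.2383047443 0.3758123486
0.0750568573 -0.715357654 0.6947156937
0.0028933443 0.9962184001 -0.0868362133
-0.7256814776 -0.6090520358 -0.320065635
0.7082840614 -0.3055334768 -0.636382733
-0.0094832166 -0.1472734602 -0.9890503509
-0.5467495117 -0.5352142607 0.6439026841
0.2562159295 0.9228174678 -0.2876826701
0.5172778799 -0.089214513 0.8511547248
0.6542365945 0.2561079777 -0.7116060583
0.5339557713 0.8219019174 0.1984149
0.0654586895 -0.9738578602 -0.2175224771
0.4616936067 -0.3490726024 -0.8154675541
0.2204133069 0.7645905871 -0.6056560148
-0.9845082969 0.1498842528 0.0909841973
0.7879168151 -0.5827572921 0.1989498204
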