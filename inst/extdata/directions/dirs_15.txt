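0.7353897846 -0.6677954306 0.115113542
0.5286377048 0.8413152168 -0.1128312145
0.8369233649 -0.1359810257 0.5301588836
-0.0192917539 0.4972898209 0.8673699685
-0.9340053723 -0.3398999189 -0.1100091347
0.4836524809 -0.065983869 -0.8727693892
-0.1303067474 0.9707422422 -0.2016919703
-0.7631642288 -0.381483736 0.5215846231
0.9328667679 -0.211633492 -0.291497613
-0.5971379363 -0.4886196785 -0.6361423542
0.1279082395 0.9145918026 0.383616106
-0.4062500404 0.6111749676 -0.6792834928
-0.2334749276 0.0748711111 -0.9694760311
0.2226947835 0.6137670337 -0.7574279251
0.5137076648 -0.7068069641 -0.4863418043
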