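0.8923668998 -0.2819875504 0.3523696037
-0.198261928 -0.0154836379 -0.9800267674
0.755178599 -0.0213100202 0.6551726235
-0.1053365913 0.6324189373 0.767431098
-0.8383467731 -0.4089787676 0.3604317629
0.5196764293 0.0926700749 -0.8493224747
-0.354955164 0.8013207599 0.4815515251
-0.7957767715 -0.1009780437 0.5971120201
0.8941659908 -0.2800389552 -0.349349917
-0.9901332891 0.1305886359 -0.050820055
0.0727099787 0.8439366601 0.5314924013
-0.4680927216 -0.2330544202 -0.8523935953
-0.4957702321 0.180763542 -0.8494329985
0.282274466 0.4304305804 -0.8573509441
0.4709996428 -0.5354017305 -0.7010736933
0.0231380488 -0.6743738506 0.7380274658
-0.4081194934 0.7692429557 -0.4916337602
0.7913982204 0.6097007202 -0.044202811
0.0541582735 0.3479140934 0.9359608245
0.2015606669 -0.9551266293 -0.2170401334
-0.1723032532 -0.0575346781 0.9833622678
0.7035881028 -0.6618550801 0.2586728329
-0.0141000203 0.9956470971 -0.0921305998
0.5924594476 -0.7964695167 -0.1209467319
-0.089502962 0.3434753193 -0.9348871188
0.5405655199 0.8359752104 0.0945217765
-0.9577732092 -0.2827865167 -0.051983321
0.596938155 0.4526036594 -0.6624309523
-0.0409469691 0.895473693 -0.4432270422
-0.6814571631 0.4403483748 -0.5845591875
0.3706815092 -0.5287050634 0.7635876994
0.7024857924 -0.589358843 -0.3989609826
-0.3214901089 -0.9213026086 0.2187364015
0.473358272 0.7454648507 0.4692697547
-0.3835655741 0.9106312054 -0.1537148598
0.3276908956 -0.2680019289 -0.9059766239
0.309907964 0.5806576748 0.7528570373
0.6902692706 -0.2426185391 -0.6816630975
-0.7766062965 -0.5433323128 -0.318861503
0.8671528983 -0.4974111796 -0.0250593176
-0.6000977499 -0.7185734193 0.3514753642
-0.9145156198 -0.1385916996 -0.3800704171
-0.2137900968 -0.9530399516 -0.2144962593
0.3133529268 0.7438585778 -0.5903256385
0.6785964674 0.3927098943 0.6207139223
-0.9632767326 -0.0672265114 0.2599587133
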