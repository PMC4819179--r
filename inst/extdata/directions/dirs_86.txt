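0.7223792208 -0.6652584781 0.1886780823
0.1742078291 0.1226024477 -0.9770467093
0.3173831467 -0.2574946589 0.912668855
-0.5308387742 0.2590705641 0.806903116
-0.9077785056 -0.3740212064 0.1898586894
0.4201788056 0.2459691156 -0.8734694989
-0.2986236207 0.8647765669 0.403714531
-0.9315904821 -0.1505915829 0.3308494353
0.9659111197 -0.1614706398 -0.2023436219
-0.8940631708 0.4272878392 0.1344475703
0.7202921829 0.2959674993 0.6273614673
-0.0471918488 0.273176631 -0.9608056295
-0.7705291636 0.2141400952 -0.6003572501
0.1396958927 0.6536686549 -0.7437757371
0.4363904544 -0.5183145028 -0.7354681825
0.5171188954 0.5290514574 0.6728243481
-0.4833764288 0.8186195047 -0.3101762959
-0.0542340569 0.9511153815 0.3040365078
-0.6080360791 -0.0451112717 0.7926267089
-0.5024317934 -0.7405167385 -0.4463151947
0.0302990535 0.3922780955 0.9193475203
0.6104632452 -0.451024421 0.6510849391
0.2958491253 0.716123342 0.6321713803
0.884797927 -0.4442255664 0.1406992346
-0.2519388692 -0.2305949071 -0.9398684988
-0.2390181634 0.8599623456 -0.450926914
-0.4091136849 -0.5199846315 0.7498279641
0.7977621048 0.3840315961 -0.4648605784
-0.5632635552 0.2219323565 -0.7959146917
-0.0671752579 0.1361050486 0.9884143364
0.3669242318 -0.4948845817 0.7876902049
0.7241252205 -0.5940030981 -0.3504325678
0.4127497445 -0.6895414253 0.5951220641
0.9494413387 0.3025945059 0.0836523125
-0.0829831001 0.9962642171 0.0239042855
0.5482740639 -0.7969472371 -0.2535165717
0.6737718821 0.0396000252 0.7378775568
0.3776499625 -0.0468418396 -0.9247628604
-0.8206000947 -0.5711280851 0.0206928731
0.7889071851 0.1343976411 -0.5996354954
-0.7411929512 -0.603458788 0.2940586681
-0.8555967456 -0.0370545814 -0.5163149882
-0.1878391552 -0.9695008995 -0.1574308028
0.3520973751 0.7387294503 -0.5747227486
0.0599108066 0.6551029834 0.753160525
-0.1553436117 -0.9812548175 0.1140497501
-0.9195352027 0.1904403354 -0.3437840741
-0.8777526754 -0.2762120313 -0.3914807205
-0.8877533514 0.0833462808 0.4527111491
-0.4359845664 -0.0136918372 -0.8998499828
-0.0615582294 -0.8394503201 0.5399386489
-0.5084257204 -0.2799397199 -0.8143322663
-0.0037586751 -0.8364149639 -0.5480838261
0.8441781263 -0.3514179863 -0.4048069787
-0.4111382574 -0.907099796 0.0901958616
0.6335873408 -0.6332200023 0.4445216645
0.2653649446 0.8953979522 -0.357552728
-0.4469307135 -0.8746329019 -0.1878036856
0.2725417353 -0.306570842 -0.9119952419
-0.2408334926 0.7348260301 0.6340583051
0.1474079724 -0.716362417 0.6819793085
0.177121526 -0.5451925883 -0.8193857496
0.5999767129 0.5860142601 -0.5446239354
-0.9947739106 -0.0783117561 0.0655143929
0.2917269397 -0.943642748 0.1563130092
0.7002486472 0.5342242918 0.4735570062
-0.2431820297 -0.8788634387 -0.4104406858
0.2870411383 0.4886373068 0.8239180586
-0.6663185765 -0.7141297179 -0.2145653759
-0.8336535614 -0.496730785 -0.2414130626
-0.0398412216 0.9544190796 -0.2957987451
-0.3277368338 0.934938129 0.1359384519
-0.1552636771 0.0218454525 -0.9876314934
-0.9791094085 0.1908486591 -0.0701537993
-0.5245153465 -0.7812122237 0.3385130912
0.6262126523 0.3402859863 -0.7014721388
-0.5441493734 0.8384019097 -0.0313639477
0.7488620008 -0.6578024731 -0.0806325621
-0.1900651372 -0.4139517817 0.8902354554
-0.0949985407 0.5139109656 -0.8525671802
-0.5069508615 0.6894316164 0.5173827117
0.8057536781 -0.4290229748 0.4082894773
0.9715689742 0.0585988267 0.2293902918
-0.6360895787 -0.7689371259 0.0642319565
-0.6648482345 0.4467941586 0.5986249284
-0.7359384687 0.173222945 0.6545138513
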