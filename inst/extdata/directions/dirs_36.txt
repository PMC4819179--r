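0.9516873323 0.3036763241 0.0455182569
0.3547565131 0.403650305 -0.8433351929
0.0574977346 0.6225325315 0.7804788644
-0.3879490878 0.4029048761 0.8289530542
-0.9234375801 0.2699417712 0.2727535075
0.7109837434 0.3042987571 -0.6339592914
-0.011469893 0.239048016 0.9709400021
-0.4066114931 -0.0018684954 0.913599257
0.9396585332 0.0323511624 0.340580744
-0.3812439461 -0.9069649965 -0.1790741431
0.0164185923 -0.6272541073 0.778641583
0.7407584056 -0.124518033 -0.660130475
-0.9481488285 0.2942924581 -0.1200239479
-0.7362677283 0.6671879684 0.1130046333
0.6752106434 -0.5346979325 -0.5081227293
0.4308405092 0.4024104696 0.807738986
-0.75410342 0.332416383 -0.5664162606
0.4446163602 0.7162088044 0.5379230806
0.4150263283 -0.3859056492 0.8239113889
0.3163243432 -0.740697202 -0.5927111986
-0.9425944168 -0.1290477204 0.3079974859
0.3890679184 -0.7180825384 0.5770473316
-0.3878616265 0.8965104913 0.2140847909
0.7143062501 -0.634986942 0.2942076896
0.0251094821 0.896707312 -0.441911202
0.7703444182 0.4317132608 0.4692474163
-0.4298029898 -0.8758229298 0.2195531499
0.0322288616 0.9062117902 0.4215939892
-0.7071781958 -0.0625495162 -0.7042631308
0.420530168 0.6993458764 -0.5779876495
-0.379526092 0.9031825379 -0.200552359
0.004394327 -0.2186190296 0.9758003944
-0.766300941 -0.5681983315 0.2998891861
0.7303148304 0.6733711784 0.1149413094
0.0031227201 0.9997590879 -0.0217259005
0.3566252575 0.0104524845 0.9341890447
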