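q_invnm,omega0_invps
0.2,0.392804847804306
0.271794871794872,0.545868538663766
0.343589743589744,0.682290267723562
0.415384615384615,0.829421033164724
0.487179487179487,0.950129897468607
0.558974358974359,1.09163360777109
0.630769230769231,1.31997821993387
0.702564102564103,1.47310236768105
0.774358974358974,1.62132985404297
0.846153846153846,1.72635110997856
0.917948717948718,1.87340859656011
0.98974358974359,2.07360059235811
1.06153846153846,2.19714689302108
1.13333333333333,2.41538669843614
1.20512820512821,2.59552627732719
1.27692307692308,2.7489824778442
1.34871794871795,3.04751430624828
1.42051282051282,3.23009977060832
1.49230769230769,3.44430526295403
1.56410256410256,3.48515929336503
1.63589743589744,3.59829451346334
1.70769230769231,3.98674911417887
1.77948717948718,4.07263839536304
1.85128205128205,4.45412663104725
1.92307692307692,4.49034575580563
1.99487179487179,4.83078439471307
2.06666666666667,5.1211270548994
2.13846153846154,5.14115045070315
2.21025641025641,5.71730236925909
2.28205128205128,5.63041299192165
2.35384615384615,6.16966164135403
2.42564102564103,6.42865403051442
2.4974358974359,6.29296024556673
2.56923076923077,6.84138609208031
2.64102564102564,6.86624457115608
2.71282051282051,7.5785097407034
2.78461538461538,7.75467005664735
2.85641025641026,8.13948149878113
2.92820512820513,8.42541675949273
3,8.55140594032519
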