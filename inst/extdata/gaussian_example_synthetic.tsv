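# synthetic example: 512 standard Gaussian draws (seed 101)
-0.32603649
0.55246186
-0.67494384
0.21435946
0.31076922
1.1739663
0.61878986
-0.11273431
0.91702829
-0.22325936
0.5264481
-0.79484444
1.4277555
-1.4668197
-0.23668338
-0.19333796
-0.84975474
0.058465498
-0.81767036
-2.0503078
-0.16375567
0.7085221
-0.26798055
-1.4639218
0.74443582
-1.4103902
0.46706761
-0.11932011
0.46723896
0.49813556
0.8949372
0.279152
1.0078658
-2.0731065
1.1898534
-0.72437422
0.16798377
0.92033516
-1.6716048
0.44846907
0.48245881
0.75821378
-2.3193274
-0.45950478
-1.1053837
0.40292827
0.56893492
-0.70608328
-0.29009063
-1.4838781
-1.1502553
-0.27447116
0.577901
-1.3969026
0.74905772
-1.0511867
0.16538087
1.1298091
1.1737225
-0.42786323
-0.25980211
-1.411173
-0.64135755
0.11245751
0.42260433
0.38683529
-0.68779833
0.14890249
-0.057649748
-0.074823365
1.5098974
1.619937
1.1531582
-0.077603595
-1.8189345
-1.0374446
0.30249225
-1.2779462
0.13833905
-0.050984124
1.8521476
1.1116753
-0.51137532
-0.5438811
-1.7289273
0.47074954
0.0053871222
1.3480458
0.72409671
1.5525492
1.3254698
-0.034265092
-0.3610134
-0.72016542
0.28201493
-0.79052566
-0.44490455
1.3649932
0.49745434
-0.81439648
0.26806584
-0.59220831
2.1334864
1.1727487
0.74676099
-0.23050869
0.087771702
-2.1837397
-0.46663159
1.6859598
-0.56792093
-0.046743016
-0.15698059
1.6022424
0.76865367
-0.77162936
-0.63068198
-0.8302806
-0.59111274
0.98108541
-0.66160527
-0.77241769
-2.0184735
-0.53358542
0.43472833
-0.77116734
-0.75394082
-0.29935782
1.6639664
-1.2443298
-0.78313437
0.24483056
-0.14388717
-1.6086314
0.95157997
-1.8191317
1.7836717
1.8871394
1.4907188
-0.38059952
-0.90937501
-0.33809411
-1.4118835
0.21754289
0.67012617
-0.28785938
0.4693035
-0.47007143
-0.23926592
-0.44746249
-0.61882966
0.25296305
-0.75336818
0.73227685
-0.40258671
-2.8230001
0.46297383
2.1328697
-0.27048669
0.24852535
0.038116475
0.39406895
-1.5040852
-1.5868908
-0.92711808
0.77619704
-0.78068444
-1.278567
-0.0014281282
-1.8509781
0.45150533
-0.43294705
0.7136029
0.96069547
0.38153521
1.2180728
-0.017137261
-0.038209493
1.2437344
-0.95585875
0.91542524
-0.93933798
0.11212482
0.55301262
0.53174196
-0.87376239
-0.18684927
-0.21371049
-0.20401127
1.7197092
0.20203348
0.51265578
1.4524
0.36386547
-0.87584895
-0.014560733
-0.72449316
1.9693701
-0.53640243
-0.02623234
-0.16403235
-1.3832751
0.42351126
-0.79048891
1.2099248
0.89451677
-0.10119854
0.29712257
0.19729772
-0.15698374
1.536571
-2.1676697
0.59844815
0.043112359
1.2950272
0.70630294
0.34554508
-0.079896653
0.45480755
1.2762524
1.2648376
0.26925353
-0.12054409
0.79527135
-0.51402764
-0.40659347
1.219719
0.08371137
0.58990215
-0.51741928
0.76946349
0.80196974
-0.69686014
1.1778532
0.58584526
-0.46689388
0.38564964
-0.53460558
1.0566684
-0.20609327
0.60701224
-0.54806386
-2.0999763
0.25081276
-0.054945281
-0.65972781
-1.4558574
0.023729426
0.54790809
-0.8089014
-0.23902325
-0.35311873
0.81959921
-0.34527961
-1.1828845
-1.0313211
-0.075089315
0.82858547
-1.0359847
-0.14715611
-0.28145388
-1.3736857
1.5584501
-0.57494504
2.1873352
0.79429162
0.20256026
-0.022050085
0.30453089
-1.1092492
0.7654731
-0.022026429
-0.90399822
0.40000174
-1.1492876
0.18816763
0.2172901
-1.0490857
-0.075123433
-1.567989
-1.1737971
-2.1483061
0.34171545
0.90497084
1.0964905
-1.4712609
-0.28059686
0.84613962
-1.2859137
-0.31243587
-0.36284324
1.4124539
-0.25520231
0.38701753
0.52494075
0.61514518
-0.33281629
0.74532876
-0.3112654
-0.23425145
-1.1658569
-0.23979867
1.1843827
0.20750839
-0.043632597
-0.9710775
0.57422258
-1.2598654
1.0616788
-0.43399368
0.23917695
-0.50232861
-1.7038766
0.52377224
1.5641722
-2.4662529
-0.14882077
2.110837
-0.34619529
0.98218255
0.3914314
-0.50999406
-1.0496464
0.046007152
-1.0088282
-0.65624967
0.094017931
0.017924275
-1.6035245
0.48307608
-0.22442282
-0.43739786
1.3277685
-0.46847787
-1.3399577
1.6654327
0.53894995
0.99938476
0.34148933
-1.0586273
-0.041599301
-1.2928277
-0.893864
0.5419092
0.96963598
-0.24498892
0.86018008
-0.67584395
-0.50004369
1.8320329
-0.32927226
0.26130789
-1.1121605
1.0622105
0.20500024
-2.0243277
1.2273748
1.1953441
0.77251555
-1.409538
-0.43242997
-0.44228811
1.3489923
-1.0746316
-0.33508242
0.75083241
1.9972066
1.7919078
-1.2329763
-3.1772097
-1.0848417
0.060763433
-0.18176615
0.34131101
1.1067916
0.68881616
0.47099175
-1.640067
-0.67902317
0.48630806
0.2261754
-0.64668074
-0.1132858
0.52052366
2.586743
0.54219234
1.0652039
-0.75014787
0.7937911
-0.74976286
0.30630227
1.3183699
-0.26654021
0.26580617
1.1398384
-0.98654482
-0.67366679
-1.9047443
-0.71792209
-0.38354201
-0.32053695
-2.0919208
-1.8518319
0.43966527
0.14190484
-0.82505912
-1.3711798
0.024881446
1.5809925
-0.75971603
-0.53854478
-0.26029128
-0.64460131
1.2152529
1.7820026
-0.064037428
0.62448114
-0.93859515
-1.8326834
-0.90148573
-0.95090208
-0.83530331
0.54609793
1.6125359
-0.65311467
-0.036646653
-0.1106327
1.2420054
-0.69242365
-1.1654426
-1.0560933
0.72348511
0.36022751
0.25622118
0.75288791
-0.99262436
1.4863263
-0.72665365
0.096650318
0.21486406
0.51847549
-0.29630289
-0.35200087
0.13371963
-0.22686301
0.86307673
1.6042122
-0.44583572
-1.1895715
0.24662155
-0.76149102
-0.39398167
-1.7282629
0.26293966
-1.6155898
-0.11726963
0.32592804
-1.9009345
-0.46980511
0.12384559
-1.1270398
-0.40179926
0.0051537578
0.67254159
-1.4463608
-1.14362
-0.30082496
-1.3889143
-2.0274797
0.50521591
0.77149963
-1.6128829
1.1424211
2.0982933
-0.16736307
-0.26692738
0.79482173
-0.45684569
-0.97170276
-0.47253457
0.94765504
1.0160396
1.7518672
1.0477024
-0.3778573
0.50810478
-1.0701846
-0.14422476
-1.0117054
1.2430232
-0.078889423
-0.80729512
-0.99620164
-0.85833121
-0.95073827
-1.1217938
-0.13507621
-0.87407374
0.25867899
-1.7451413
-1.2723581
-0.66307158
-0.29654313
-0.57396643
-0.026174082
0.25972722
0.53341757
-0.5420686
0.33766845
-0.23791286
1.1256978
0.2046879
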