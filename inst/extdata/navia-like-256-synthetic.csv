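# navia-like: SYNTHETIC approximation of the recommended relaxometry colormap look,
# built by this package from its preset anchors (256 entries, perceptually equalized).
# Not the published table; load the published deposit for exact cross-checks.
0.010129,0.118768,0.275944
0.010771,0.123029,0.280885
0.011328,0.127279,0.285860
0.011806,0.131519,0.290868
0.012207,0.135753,0.295905
0.012535,0.139982,0.300969
0.012793,0.144208,0.306059
0.012984,0.148431,0.311171
0.013111,0.152653,0.316304
0.013176,0.156871,0.321450
0.013184,0.161088,0.326611
0.013136,0.165309,0.331788
0.013037,0.169533,0.336978
0.012888,0.173760,0.342181
0.012694,0.177992,0.347392
0.012458,0.182225,0.352606
0.012184,0.186464,0.357827
0.011877,0.190708,0.363051
0.011539,0.194959,0.368276
0.011178,0.199216,0.373499
0.010797,0.203478,0.378719
0.010403,0.207747,0.383932
0.010001,0.212024,0.389137
0.009598,0.216306,0.394330
0.009202,0.220594,0.399507
0.008821,0.224889,0.404666
0.008462,0.229193,0.409808
0.008136,0.233503,0.414925
0.007853,0.237819,0.420014
0.007623,0.242140,0.425069
0.007459,0.246466,0.430087
0.007375,0.250799,0.435065
0.007384,0.255141,0.440002
0.007502,0.259487,0.444887
0.007746,0.263837,0.449715
0.008136,0.268191,0.454479
0.008691,0.272547,0.459172
0.009435,0.276905,0.463788
0.010393,0.281265,0.468316
0.011591,0.285626,0.472750
0.013062,0.289991,0.477082
0.014838,0.294355,0.481296
0.016958,0.298716,0.485379
0.019462,0.303071,0.489315
0.022396,0.307417,0.493086
0.025812,0.311751,0.496671
0.029766,0.316068,0.500047
0.034278,0.320360,0.503193
0.038984,0.324623,0.506178
0.043642,0.328851,0.509018
0.048070,0.333038,0.511710
0.052304,0.337183,0.514254
0.056367,0.341281,0.516648
0.060275,0.345329,0.518893
0.064040,0.349323,0.520989
0.067674,0.353261,0.522936
0.071186,0.357140,0.524736
0.074583,0.360955,0.526391
0.077872,0.364706,0.527903
0.081056,0.368387,0.529276
0.084142,0.371998,0.530513
0.087135,0.375539,0.531620
0.090040,0.379008,0.532600
0.092860,0.382406,0.533459
0.095600,0.385733,0.534203
0.098265,0.388989,0.534836
0.100859,0.392177,0.535364
0.103385,0.395298,0.535793
0.105849,0.398353,0.536128
0.108254,0.401347,0.536374
0.110604,0.404280,0.536536
0.112903,0.407156,0.536619
0.115155,0.409978,0.536628
0.117363,0.412747,0.536566
0.119531,0.415468,0.536438
0.121662,0.418141,0.536247
0.123758,0.420770,0.535997
0.125823,0.423357,0.535692
0.127858,0.425904,0.535334
0.129866,0.428411,0.534927
0.131849,0.430882,0.534474
0.133811,0.433320,0.533977
0.135752,0.435724,0.533439
0.137675,0.438097,0.532863
0.139581,0.440441,0.532250
0.141472,0.442757,0.531604
0.143349,0.445045,0.530927
0.145213,0.447307,0.530220
0.147066,0.449543,0.529488
0.148910,0.451756,0.528730
0.150747,0.453948,0.527949
0.152577,0.456119,0.527147
0.154403,0.458271,0.526325
0.156225,0.460405,0.525485
0.158043,0.462520,0.524630
0.159861,0.464620,0.523761
0.161680,0.466706,0.522877
0.163502,0.468780,0.521982
0.165328,0.470842,0.521076
0.167159,0.472894,0.520161
0.168996,0.474937,0.519237
0.170842,0.476974,0.518306
0.172699,0.479005,0.517369
0.174567,0.481032,0.516427
0.176449,0.483055,0.515480
0.178346,0.485078,0.514530
0.180260,0.487100,0.513578
0.182193,0.489125,0.512624
0.184146,0.491152,0.511670
0.186121,0.493184,0.510717
0.188121,0.495222,0.509764
0.190148,0.497268,0.508814
0.192202,0.499322,0.507867
0.194286,0.501387,0.506925
0.196402,0.503463,0.505988
0.198553,0.505554,0.505057
0.200741,0.507660,0.504133
0.202967,0.509783,0.503218
0.205234,0.511923,0.502314
0.207543,0.514082,0.501421
0.209898,0.516263,0.500541
0.212303,0.518468,0.499674
0.214759,0.520697,0.498823
0.217267,0.522952,0.497990
0.219830,0.525234,0.497176
0.222451,0.527545,0.496383
0.225133,0.529887,0.495612
0.227880,0.532262,0.494867
0.230695,0.534673,0.494148
0.233579,0.537118,0.493460
0.236536,0.539601,0.492803
0.239567,0.542123,0.492180
0.242675,0.544685,0.491595
0.245865,0.547289,0.491050
0.249138,0.549936,0.490548
0.252497,0.552627,0.490092
0.255945,0.555365,0.489684
0.259480,0.558143,0.489317
0.263067,0.560907,0.488895
0.266695,0.563650,0.488402
0.270362,0.566373,0.487841
0.274065,0.569079,0.487217
0.277801,0.571770,0.486532
0.281569,0.574448,0.485789
0.285368,0.577115,0.484991
0.289195,0.579774,0.484139
0.293050,0.582425,0.483238
0.296931,0.585070,0.482287
0.300838,0.587712,0.481291
0.304772,0.590352,0.480249
0.308732,0.592992,0.479165
0.312717,0.595632,0.478040
0.316728,0.598276,0.476875
0.320764,0.600923,0.475672
0.324826,0.603575,0.474433
0.328913,0.606234,0.473159
0.333028,0.608901,0.471852
0.337170,0.611577,0.470513
0.341339,0.614264,0.469145
0.345535,0.616962,0.467748
0.349760,0.619672,0.466325
0.354013,0.622396,0.464876
0.358296,0.625135,0.463405
0.362610,0.627890,0.461913
0.366954,0.630661,0.460401
0.371331,0.633451,0.458872
0.375744,0.636262,0.457327
0.380191,0.639093,0.455769
0.384673,0.641945,0.454200
0.389193,0.644820,0.452623
0.393751,0.647720,0.451041
0.398349,0.650644,0.449456
0.402988,0.653595,0.447871
0.407671,0.656573,0.446290
0.412398,0.659581,0.444716
0.417172,0.662619,0.443152
0.421995,0.665688,0.441603
0.426869,0.668791,0.440073
0.431796,0.671928,0.438566
0.436779,0.675102,0.437088
0.441820,0.678312,0.435643
0.446921,0.681563,0.434238
0.452086,0.684854,0.432878
0.457317,0.688187,0.431572
0.462620,0.691566,0.430324
0.467999,0.694994,0.429144
0.473454,0.698470,0.428041
0.478989,0.701996,0.427024
0.484608,0.705575,0.426104
0.490313,0.709207,0.425291
0.496109,0.712896,0.424599
0.502007,0.716647,0.424039
0.508008,0.720462,0.423628
0.514111,0.724339,0.423380
0.520321,0.728279,0.423314
0.526650,0.732292,0.423447
0.533100,0.736378,0.423800
0.539667,0.740532,0.424396
0.546362,0.744762,0.425256
0.553190,0.749071,0.426408
0.560140,0.753451,0.427875
0.567231,0.757913,0.429688
0.574446,0.762448,0.431874
0.581790,0.767057,0.434461
0.589256,0.771736,0.437478
0.596830,0.776477,0.440951
0.604534,0.781257,0.444919
0.612371,0.786041,0.449383
0.620315,0.790814,0.454313
0.628337,0.795563,0.459671
0.636415,0.800280,0.465419
0.644526,0.804956,0.471522
0.652651,0.809583,0.477940
0.660777,0.814160,0.484641
0.668882,0.818678,0.491585
0.676968,0.823143,0.498753
0.685009,0.827543,0.506100
0.693010,0.831887,0.513613
0.700966,0.836175,0.521269
0.708856,0.840398,0.529032
0.716694,0.844568,0.536898
0.724476,0.848685,0.544850
0.732183,0.852742,0.552854
0.739829,0.856748,0.560913
0.747414,0.860706,0.569013
0.754933,0.864616,0.577141
0.762379,0.868476,0.585277
0.769763,0.872293,0.593422
0.777085,0.876068,0.601569
0.784345,0.879804,0.609708
0.791542,0.883500,0.617831
0.798672,0.887158,0.625926
0.805744,0.890781,0.633995
0.812759,0.894373,0.642031
0.819717,0.897933,0.650031
0.826620,0.901465,0.657988
0.833469,0.904969,0.665899
0.840266,0.908447,0.673758
0.847009,0.911899,0.681560
0.853702,0.915328,0.689302
0.860347,0.918736,0.696982
0.866945,0.922124,0.704595
0.873497,0.925493,0.712139
0.880006,0.928844,0.719610
0.886471,0.932180,0.727004
0.892894,0.935500,0.734317
0.899276,0.938807,0.741548
0.905620,0.942102,0.748692
0.911927,0.945386,0.755748
0.918198,0.948661,0.762711
0.924436,0.951928,0.769581
0.930643,0.955189,0.776355
0.936822,0.958447,0.783031
0.942977,0.961704,0.789608
0.949111,0.964962,0.796085
0.955229,0.968225,0.802461
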