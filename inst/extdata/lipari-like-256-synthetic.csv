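# lipari-like: SYNTHETIC approximation of the recommended relaxometry colormap look,
# built by this package from its preset anchors (256 entries, perceptually equalized).
# Not the published table; load the published deposit for exact cross-checks.
0.104799,0.104237,0.265090
0.110660,0.107750,0.271802
0.116378,0.111274,0.278618
0.121971,0.114808,0.285524
0.127456,0.118348,0.292506
0.132848,0.121892,0.299554
0.138161,0.125440,0.306660
0.143405,0.128991,0.313814
0.148592,0.132543,0.321007
0.153733,0.136098,0.328238
0.158840,0.139656,0.335502
0.163922,0.143218,0.342794
0.168986,0.146782,0.350109
0.174041,0.150351,0.357442
0.179096,0.153923,0.364788
0.184156,0.157500,0.372145
0.189231,0.161080,0.379505
0.194326,0.164663,0.386866
0.199449,0.168250,0.394220
0.204606,0.171841,0.401564
0.209804,0.175434,0.408890
0.215050,0.179030,0.416193
0.220351,0.182627,0.423466
0.225714,0.186226,0.430701
0.231144,0.189824,0.437890
0.236647,0.193420,0.445023
0.242231,0.197013,0.452091
0.247900,0.200599,0.459080
0.253660,0.204178,0.465979
0.259517,0.207745,0.472774
0.265474,0.211298,0.479450
0.271537,0.214831,0.485988
0.277708,0.218342,0.492373
0.283995,0.221828,0.498586
0.290392,0.225278,0.504602
0.296900,0.228686,0.510395
0.303514,0.232045,0.515940
0.310229,0.235346,0.521209
0.317037,0.238579,0.526176
0.323928,0.241735,0.530811
0.330884,0.244801,0.535084
0.337887,0.247767,0.538967
0.344914,0.250620,0.542438
0.351949,0.253359,0.545582
0.358969,0.255984,0.548455
0.365968,0.258501,0.551068
0.372939,0.260913,0.553433
0.379874,0.263227,0.555561
0.386766,0.265446,0.557462
0.393612,0.267575,0.559148
0.400407,0.269618,0.560628
0.407149,0.271581,0.561914
0.413830,0.273466,0.563013
0.420455,0.275279,0.563936
0.427022,0.277024,0.564690
0.433530,0.278705,0.565286
0.439980,0.280326,0.565729
0.446371,0.281890,0.566028
0.452703,0.283401,0.566189
0.458977,0.284863,0.566219
0.465194,0.286277,0.566124
0.471354,0.287649,0.565909
0.477458,0.288980,0.565581
0.483506,0.290273,0.565143
0.489500,0.291531,0.564602
0.495440,0.292757,0.563962
0.501327,0.293953,0.563227
0.507162,0.295122,0.562403
0.512945,0.296266,0.561492
0.518679,0.297387,0.560499
0.524362,0.298488,0.559428
0.529997,0.299572,0.558283
0.535583,0.300639,0.557067
0.541122,0.301692,0.555784
0.546615,0.302734,0.554437
0.552061,0.303766,0.553031
0.557461,0.304791,0.551567
0.562817,0.305811,0.550050
0.568128,0.306827,0.548483
0.573395,0.307842,0.546869
0.578619,0.308857,0.545211
0.583801,0.309875,0.543513
0.588939,0.310898,0.541777
0.594036,0.311927,0.540008
0.599092,0.312965,0.538207
0.604106,0.314014,0.536380
0.609080,0.315075,0.534528
0.614013,0.316150,0.532654
0.618907,0.317242,0.530763
0.623761,0.318352,0.528857
0.628576,0.319483,0.526940
0.633352,0.320636,0.525014
0.638090,0.321813,0.523084
0.642791,0.323017,0.521152
0.647454,0.324249,0.519222
0.652080,0.325511,0.517297
0.656670,0.326805,0.515379
0.661224,0.328134,0.513474
0.665743,0.329499,0.511583
0.670228,0.330902,0.509711
0.674678,0.332346,0.507860
0.679096,0.333832,0.506033
0.683481,0.335362,0.504235
0.687834,0.336939,0.502469
0.692157,0.338564,0.500736
0.696450,0.340241,0.499042
0.700715,0.341970,0.497390
0.704952,0.343755,0.495782
0.709162,0.345597,0.494223
0.713347,0.347499,0.492715
0.717508,0.349464,0.491262
0.721645,0.351493,0.489869
0.725761,0.353590,0.488537
0.729857,0.355757,0.487272
0.733933,0.357996,0.486078
0.737991,0.360311,0.484957
0.742031,0.362703,0.483915
0.746056,0.365177,0.482956
0.750066,0.367734,0.482083
0.754062,0.370378,0.481303
0.758045,0.373111,0.480619
0.762015,0.375937,0.480037
0.765973,0.378857,0.479561
0.769920,0.381875,0.479197
0.773848,0.384987,0.478936
0.777705,0.388140,0.478665
0.781482,0.391321,0.478361
0.785182,0.394526,0.478026
0.788807,0.397755,0.477665
0.792362,0.401004,0.477281
0.795849,0.404274,0.476876
0.799268,0.407560,0.476454
0.802624,0.410862,0.476016
0.805920,0.414180,0.475566
0.809157,0.417512,0.475105
0.812338,0.420857,0.474636
0.815466,0.424215,0.474160
0.818542,0.427585,0.473679
0.821569,0.430967,0.473196
0.824548,0.434360,0.472712
0.827482,0.437763,0.472228
0.830372,0.441178,0.471746
0.833218,0.444599,0.471267
0.836023,0.448030,0.470795
0.838789,0.451471,0.470328
0.841518,0.454923,0.469869
0.844212,0.458385,0.469419
0.846873,0.461857,0.468980
0.849500,0.465340,0.468552
0.852095,0.468831,0.468138
0.854660,0.472333,0.467738
0.857196,0.475847,0.467354
0.859706,0.479374,0.466986
0.862190,0.482913,0.466637
0.864649,0.486464,0.466307
0.867084,0.490029,0.465999
0.869497,0.493608,0.465712
0.871888,0.497202,0.465450
0.874261,0.500812,0.465212
0.876614,0.504439,0.465001
0.878949,0.508083,0.464819
0.881268,0.511746,0.464666
0.883572,0.515428,0.464546
0.885861,0.519131,0.464458
0.888136,0.522855,0.464407
0.890399,0.526601,0.464392
0.892650,0.530370,0.464418
0.894893,0.534167,0.464485
0.897126,0.537991,0.464597
0.899350,0.541842,0.464755
0.901567,0.545721,0.464963
0.903778,0.549631,0.465224
0.905983,0.553572,0.465540
0.908184,0.557548,0.465916
0.910384,0.561564,0.466354
0.912582,0.565616,0.466859
0.914779,0.569708,0.467435
0.916976,0.573841,0.468085
0.919174,0.578018,0.468816
0.921374,0.582241,0.469633
0.923578,0.586513,0.470540
0.925788,0.590836,0.471546
0.928003,0.595214,0.472655
0.930226,0.599649,0.473876
0.932458,0.604145,0.475218
0.934701,0.608705,0.476688
0.936957,0.613333,0.478298
0.939225,0.618034,0.480058
0.941509,0.622810,0.481980
0.943810,0.627667,0.484077
0.946130,0.632609,0.486364
0.948469,0.637640,0.488858
0.950829,0.642764,0.491574
0.953213,0.647987,0.494534
0.955619,0.653311,0.497758
0.958023,0.658740,0.501271
0.960379,0.664270,0.505087
0.962677,0.669884,0.509193
0.964913,0.675571,0.513585
0.967080,0.681324,0.518251
0.969178,0.687135,0.523184
0.971200,0.692990,0.528368
0.973143,0.698879,0.533787
0.975006,0.704794,0.539428
0.976787,0.710723,0.545272
0.978484,0.716659,0.551302
0.980098,0.722594,0.557503
0.981628,0.728521,0.563857
0.983074,0.734429,0.570343
0.984437,0.740314,0.576947
0.985720,0.746173,0.583654
0.986924,0.752000,0.590451
0.988052,0.757791,0.597321
0.989103,0.763535,0.604242
0.990082,0.769235,0.611209
0.990991,0.774888,0.618209
0.991834,0.780491,0.625230
0.992612,0.786042,0.632261
0.993328,0.791538,0.639291
0.993985,0.796976,0.646310
0.994586,0.802351,0.653301
0.995134,0.807664,0.660261
0.995631,0.812915,0.667182
0.996082,0.818100,0.674055
0.996488,0.823220,0.680874
0.996852,0.828273,0.687631
0.997177,0.833258,0.694319
0.997467,0.838173,0.700933
0.997722,0.843018,0.707467
0.997947,0.847793,0.713917
0.998144,0.852498,0.720279
0.998314,0.857133,0.726551
0.998461,0.861699,0.732729
0.998587,0.866188,0.738803
0.998694,0.870609,0.744777
0.998784,0.874962,0.750654
0.998859,0.879249,0.756433
0.998921,0.883474,0.762115
0.998972,0.887637,0.767702
0.999013,0.891742,0.773194
0.999047,0.895778,0.778577
0.999074,0.899755,0.783863
0.999096,0.903681,0.789060
0.999114,0.907557,0.794171
0.999131,0.911386,0.799197
0.999146,0.915153,0.804117
0.999162,0.918879,0.808959
0.999178,0.922567,0.813724
0.999197,0.926218,0.818414
0.999220,0.929819,0.823013
0.999247,0.933392,0.827544
0.999279,0.936937,0.832011
0.999318,0.940452,0.836408
0.999364,0.943940,0.840738
0.999419,0.947411,0.845013
0.999483,0.950866,0.849234
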