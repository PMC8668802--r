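well_id,sample_id,dilution_fold,n,k,printed_conc
1:1 Rep1,High,1,2422,148,74.2
1:1 Rep2,High,1,10485,761,88.6
1:1 Rep3,High,1,12917,1028,97.6
1:1 Rep4,High,1,10440,772,90.4
1:1 Rep5,High,1,10874,786,88.3
1:1 Rep6,High,1,10762,759,86.0
1:1 Rep7,High,1,12396,966,95.4
1:1 Rep8,High,1,12302,936,93.1
1:1 Rep9,High,1,10811,762,86.0
1:1 Rep10,High,1,14650,1249,105.0
1:10 Rep1,High,0.1,12695,113,10.5
1:10 Rep2,High,0.1,15226,101,7.83
1:10 Rep3,High,0.1,15248,130,10.1
1:10 Rep4,High,0.1,17553,124,8.34
1:10 Rep5,High,0.1,15321,121,9.33
1:10 Rep6,High,0.1,13965,93,7.86
1:10 Rep7,High,0.1,11404,69,7.14
1:10 Rep8,High,0.1,11477,84,8.64
1:10 Rep9,High,0.1,12831,99,9.11
1:10 Rep10,High,0.1,10239,67,7.72
1:100 Rep1,High,0.01,11272,10,1.04
1:100 Rep2,High,0.01,11613,4,0.41
1:100 Rep3,High,0.01,11414,4,0.41
1:100 Rep4,High,0.01,12886,9,0.82
1:100 Rep5,High,0.01,12001,13,1.28
1:100 Rep6,High,0.01,11554,7,0.71
1:100 Rep7,High,0.01,12556,7,0.66
1:100 Rep8,High,0.01,10979,8,0.86
1:100 Rep9,High,0.01,11371,14,1.45
1:100 Rep10,High,0.01,12508,10,0.94
1:1000 Rep1,High,0.001,13182,2,0.18
1:1000 Rep2,High,0.001,13343,3,0.27
1:1000 Rep3,High,0.001,12921,1,0.09
1:1000 Rep4,High,0.001,12112,3,0.29
1:1000 Rep5,High,0.001,14343,4,0.33
1:1000 Rep6,High,0.001,11181,0,0.0
1:1000 Rep7,High,0.001,11573,3,0.31
1:1000 Rep8,High,0.001,12788,3,0.27
1:1000 Rep9,High,0.001,12891,2,0.18
1:1000 Rep10,High,0.001,12678,3,0.28
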