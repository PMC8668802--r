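well_id,sample_id,cartridge_id,conc_copies_ul,ci_low,ci_high,n,amp_pos_mean,amp_neg_mean,lambda
High_a,High,1,83.2,78.1,88.4,14522,17024,5604,0.071
High_b,High,1,94.2,88.9,99.6,15489,16819,5569,0.080
High_c,High,2,80.3,75.2,85.5,14140,16703,5190,0.068
High_d,High,2,91.9,86.7,97.1,15815,16474,5130,0.078
Intermediate_a,Intermediate,1,46.6,42.9,50.3,15638,16599,5284,0.040
Intermediate_b,Intermediate,1,49.5,45.7,53.4,15379,16761,5293,0.042
Intermediate_c,Intermediate,2,53.3,49.3,57.3,15127,16477,4913,0.045
Intermediate_d,Intermediate,2,49.6,45.7,53.5,15211,16608,4881,0.042
Low_a,Low,1,1.86,1.2,2.74,14527,16867,5348,0.002
Low_b,Low,1,2.77,1.92,3.86,13584,17252,5379,0.002
Low_c,Low,2,1.96,1.27,2.85,14451,16716,4890,0.002
Low_d,Low,2,1.22,0.69,1.98,13490,17150,4921,0.001
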