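month,population,prevalence_pct,n_infected,mean_load,se_load,variance,vmr
March,Herslev,85.2,23,101.10,46.10,48915.70,483.83
March,Lammefjord,40.0,10,0.40,0.10,0.10,0.30
March,Vellerup,69.2,18,1.30,0.50,3.70,2.80
March,Lynaes,72.0,18,18.20,13.60,3333.00,183.10
May,Herslev,92.9,26,104.90,43.50,49265.50,469.60
May,Lammefjord,36.0,9,1.62,0.50,2.16,1.30
May,Vellerup,18.5,5,59.70,58.20,16937.52,283.71
May,Lynaes,56.0,14,1.10,0.30,1.50,1.38
August,Herslev,100.0,24,150.45,64.30,99181.60,659.20
August,Lammefjord,44.0,11,0.75,0.20,0.44,0.59
August,Vellerup,80.0,20,351.60,126.00,317762.80,903.76
August,Lynaes,48.0,12,2.61,1.41,24.01,17.03
October,Herslev,87.0,20,210.20,106.60,227294.40,1081.30
October,Lammefjord,36.0,9,72.20,65.20,38222.87,529.40
October,Vellerup,88.5,23,140.40,8.40,148597.40,1058.39
October,Lynaes,64.0,16,250.40,197.60,624783.70,2495.14
November,Herslev,92.9,26,349.20,145.20,548069.20,1569.50
November,Lammefjord,50.0,12,24.40,23.90,6826.50,279.78
November,Vellerup,95.5,21,164.50,10.10,227784.40,1384.71
November,Lynaes,63.2,12,19.00,15.60,2933.20,154.38
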