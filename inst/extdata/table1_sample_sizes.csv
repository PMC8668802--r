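month,population,n_hosts
March,Herslev,27
March,Lammefjord,25
March,Vellerup,26
March,Lynaes,25
May,Herslev,28
May,Lammefjord,25
May,Vellerup,27
May,Lynaes,25
August,Herslev,25
August,Lammefjord,25
August,Vellerup,25
August,Lynaes,25
October,Herslev,23
October,Lammefjord,25
October,Vellerup,26
October,Lynaes,25
November,Herslev,28
November,Lammefjord,24
November,Vellerup,22
November,Lynaes,19
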