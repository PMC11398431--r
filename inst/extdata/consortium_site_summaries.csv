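site,encounters,hospitals,age_mean,age_sd,female_n,asian_n,black_n,white_n,other_n,hispanic_n,non_hispanic_n,imv_n,deaths_n
site_a,19923,4,61.2,16.5,9406,671,9019,9048,1185,761,19162,9852,1529
site_b,18325,5,60.6,17.4,8428,765,5881,10128,1551,1208,17117,6595,1851
site_c,11576,11,61.8,17.3,5128,756,824,9503,493,224,11352,4059,1193
site_d,6877,1,59.0,16.2,2834,135,826,5429,487,201,6676,3358,817
site_e,10625,8,63.2,17.5,4840,352,1272,8005,996,1004,9851,3034,809
site_f,9046,2,59.9,17.3,3814,276,775,7525,470,788,8258,2563,983
site_g,9905,1,59.6,16.9,4687,329,4012,3717,1847,1983,7922,2862,730
site_h,8079,1,56.4,18.5,3422,150,5307,2015,607,497,7582,3466,1008
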