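population,category,pct_users,mean,sd,pct_of_total,median,iqr
total,acute_hospital,76,15111,22537,54,8218,18387
total,rehabilitation,21,3496,16894,12,0,0
total,hospital_at_home,6.3,986,8265,4,0,0
total,nursing_services,66,1297,3158,5,30,586
total,outpatient_visits,77,308,307,1,248,328
total,physio_other,42,406,862,1,0,364
total,equipment_devices,76,1178,2770,4,216,1323
total,pharmacy,89,2409,6580,9,811,1535
total,expensive_hospital_drugs,9,765,20158,3,0,0
total,transportation,82,992,2859,4,270,822
total,procedures_imaging,70,1137,2606,4,332,979
total,total,95,28085,35895,100,16875,31657
dementia,acute_hospital,NA,9434,13765,NA,6551,12743
dementia,rehabilitation,NA,4998,19361,NA,0,0
dementia,hospital_at_home,NA,516,5540,NA,0,0
dementia,nursing_services,NA,1294,3404,NA,6,769
dementia,outpatient_visits,NA,280,295,NA,253,309
dementia,physio_other,NA,616,1099,NA,55,998
dementia,equipment_devices,NA,848,1879,NA,124,1102
dementia,pharmacy,NA,998,2398,NA,690,954
dementia,expensive_hospital_drugs,NA,177,NA,NA,0,0
dementia,transportation,NA,614,2065,NA,304,571
dementia,procedures_imaging,NA,940,1443,NA,238,499
dementia,total,NA,20715,29435,NA,13938,22693
breast_cancer,acute_hospital,NA,22754,22806,NA,17316,24629
breast_cancer,rehabilitation,NA,4095,15567,NA,0,0
breast_cancer,hospital_at_home,NA,2324,12155,NA,0,0
breast_cancer,nursing_services,NA,1060,3797,NA,156,801
breast_cancer,outpatient_visits,NA,381,245,NA,331,386
breast_cancer,physio_other,NA,391,748,NA,73,516
breast_cancer,equipment_devices,NA,1300,3527,NA,428,1381
breast_cancer,pharmacy,NA,6650,17079,NA,3336,7671
breast_cancer,expensive_hospital_drugs,NA,2658,NA,NA,0,0
breast_cancer,transportation,NA,1185,2910,NA,1016,2332
breast_cancer,procedures_imaging,NA,3404,3407,NA,1456,2850
breast_cancer,total,NA,46202,39682,NA,39041,40626
cold,acute_hospital,NA,19141,24845,NA,14887,21392
cold,rehabilitation,NA,3682,15894,NA,0,0
cold,hospital_at_home,NA,1036,7282,NA,0,0
cold,nursing_services,NA,1247,3346,NA,109,1128
cold,outpatient_visits,NA,354,341,NA,322,331
cold,physio_other,NA,498,971,NA,52,624
cold,equipment_devices,NA,1908,3742,NA,891,2797
cold,pharmacy,NA,2764,6898,NA,1428,1996
cold,expensive_hospital_drugs,NA,808,NA,NA,0,0
cold,transportation,NA,1864,1367,NA,514,1129
cold,procedures_imaging,NA,1142,3743,NA,536,2151
cold,total,NA,34444,35884,NA,28431,34745
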