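disease,cluster,name,n,mean,sd,median,iqr
dementia,1,few and late hospitalizations,6725,16139,15379,12588,12926
dementia,2,acute care during the last 3 months of life,2664,42045,31991,34819,28199
dementia,3,early and repeated hospitalizations,611,76759,54026,64352,51294
breast_cancer,1,few and late hospitalizations,5848,35872,33586,30771,30161
breast_cancer,2,acute care during the last 3 months of life,3609,62643,37709,55288,40664
breast_cancer,3,early and repeated hospitalizations,543,91246,46947,81783,55381
cold,1,few and late hospitalizations,8410,30512,26001,24304,26207
cold,2,early and repeated hospitalizations,1590,82164,47747,71333,51821
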