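experiment,setting,tp,fn,tn,fp,accuracy,specificity,recall,precision,f1
chestxray14,FTS_100k,39267,10733,38548,11452,0.7782,0.7710,0.7853,0.7742,0.7797
chestxray14,FTS_200k,44002,5998,43426,6574,0.8743,0.8685,0.8800,0.8700,0.8750
chestxray14,FTS_400k,41094,8906,46452,3548,0.8755,0.9290,0.8219,0.9205,0.8684
chestxray14,FTS_800k,47662,2338,47705,2295,0.9537,0.9541,0.9532,0.9541,0.9536
chestxray14,RNP_800k,46434,3566,49111,889,0.9555,0.9822,0.9287,0.9812,0.9542
chestxray14,foreign_material,334,9,338,5,0.9796,0.9854,0.9738,0.9853,0.9795
chestxray14,no_foreign_material,214,4,216,2,0.9862,0.9908,0.9817,0.9907,0.9862
chexpert,external,7625,618,7937,306,0.9440,0.9629,0.9250,0.9614,0.9429
covid19,external,664,110,757,17,0.9180,0.9780,0.8579,0.9750,0.9127
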