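region,deltaic,estuarine,lagoonal,open_coast
Australia and New Zealand,213,5772,335,3661
East and Southern Africa,2485,3278,441,1071
East Asia,1,130,1,27
Middle East,12,0,84,222
North and Central America and the Caribbean,1950,2663,11905,4433
Pacific Islands,2598,695,334,2674
South America,12963,3154,809,2016
South Asia,7041,516,212,645
Southeast Asia,16533,13522,588,13124
West and Central Africa,11176,7680,285,618
Atlantic East Pacific,26089,13497,12999,7068
Indo West Pacific,28883,23914,1994,21425
Total,54972,37411,14993,28493
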