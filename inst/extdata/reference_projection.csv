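year,group,demand,supply,surplus_deficit,fte_vacancy_rate,pct_graduates_hired
2010,RN,1381,1293,-88,0.03,0.70
2011,RN,1916,1107,-809,0.05,0.70
2012,RN,3244,1107,-2137,0.09,0.70
2013,RN,4481,1107,-3374,0.13,0.70
2014,RN,5163,1107,-4056,0.14,0.70
2015,RN,5865,1107,-4758,0.15,0.70
2016,RN,6591,1107,-5484,0.17,0.70
2017,RN,7342,1107,-6235,0.18,0.70
2018,RN,8120,1107,-7013,0.20,0.70
2019,RN,8909,1107,-7802,0.21,0.70
2020,RN,9725,1107,-8618,0.22,0.70
2010,LPN,250,799,549,,0.31
2011,LPN,620,799,179,,0.77
2012,LPN,632,799,167,,0.79
2013,LPN,642,799,157,,0.80
2014,LPN,651,799,148,,0.81
2015,LPN,665,799,134,,0.83
2016,LPN,680,799,119,,0.85
2017,LPN,694,799,105,,0.87
2018,LPN,710,799,89,,0.89
2019,LPN,723,799,76,,0.90
2020,LPN,738,798,60,,0.90
2010,HCA,1526,,,,
2011,HCA,2669,,,,
2012,HCA,2733,,,,
2013,HCA,2794,,,,
2014,HCA,2856,,,,
2015,HCA,2923,,,,
2016,HCA,2991,,,,
2017,HCA,3059,,,,
2018,HCA,3130,,,,
2019,HCA,3194,,,,
2020,HCA,3264,,,,
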