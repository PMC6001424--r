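group,n_cases,parameter,feature,mean,sd
HB,4,ADC,mean,1181,71
HB,4,ADC,median,1104,77
HB,4,ADC,p5,767,110
HB,4,ADC,p25,972,66
HB,4,ADC,p75,1301,96
HB,4,ADC,p90,1632,96
HB,4,ADC,kurtosis,2.19,0.040
HB,4,ADC,skewness,0.031,0.0016
HB,4,ADC,entropy,6.91,0.22
HB,4,D,mean,962,61
HB,4,D,median,938,51
HB,4,D,p5,386,131
HB,4,D,p25,791,60
HB,4,D,p75,1096,65
HB,4,D,p90,1356,71
HB,4,D,kurtosis,2.21,0.0065
HB,4,D,skewness,0.034,0.00034
HB,4,D,entropy,7.01,0.084
HB,4,Dstar,mean,18723,1878
HB,4,Dstar,median,16144,1933
HB,4,Dstar,p5,5068,589
HB,4,Dstar,p25,11042,1295
HB,4,Dstar,p75,24000,2616
HB,4,Dstar,p90,33940,3412
HB,4,Dstar,kurtosis,2.22,0.030
HB,4,Dstar,skewness,0.0073,0.00043
HB,4,Dstar,entropy,9.78,0.18
HB,4,f,mean,16.6,1.53
HB,4,f,median,14.3,1.43
HB,4,f,p5,4.00,0.94
HB,4,f,p25,9.00,1.17
HB,4,f,p75,20.8,1.78
HB,4,f,p90,31.3,2.48
HB,4,f,kurtosis,2.15,0.028
HB,4,f,skewness,0.22,0.0084
HB,4,f,entropy,3.60,0.070
NB,11,ADC,mean,1164,190
NB,11,ADC,median,1070,201
NB,11,ADC,p5,625,124
NB,11,ADC,p25,825,139
NB,11,ADC,p75,1416,271
NB,11,ADC,p90,1770,352
NB,11,ADC,kurtosis,2.22,0.075
NB,11,ADC,skewness,0.033,0.0057
NB,11,ADC,entropy,7.09,0.39
NB,11,D,mean,885,88
NB,11,D,median,817,85
NB,11,D,p5,374,102
NB,11,D,p25,616,76
NB,11,D,p75,1098,114
NB,11,D,p90,1413,157
NB,11,D,kurtosis,2.15,0.057
NB,11,D,skewness,0.030,0.0064
NB,11,D,entropy,7.04,0.23
NB,11,Dstar,mean,19348,1213
NB,11,Dstar,median,16957,1318
NB,11,Dstar,p5,5120,608
NB,11,Dstar,p25,10651,1457
NB,11,Dstar,p75,24127,1762
NB,11,Dstar,p90,35328,2118
NB,11,Dstar,kurtosis,2.22,0.016
NB,11,Dstar,skewness,0.0073,0.00019
NB,11,Dstar,entropy,9.30,0.56
NB,11,f,mean,21.1,1.85
NB,11,f,median,17.1,1.75
NB,11,f,p5,3.82,0.47
NB,11,f,p25,9.72,1.09
NB,11,f,p75,28.6,3.04
NB,11,f,p90,43.1,4.27
NB,11,f,kurtosis,2.20,0.019
NB,11,f,skewness,0.21,0.0064
NB,11,f,entropy,3.88,0.12
W,8,ADC,mean,1033,191
W,8,ADC,median,939,178
W,8,ADC,p5,643,103
W,8,ADC,p25,795,138
W,8,ADC,p75,1180,243
W,8,ADC,p90,1511,317
W,8,ADC,kurtosis,2.19,0.054
W,8,ADC,skewness,0.035,0.0029
W,8,ADC,entropy,6.95,0.32
W,8,D,mean,935,94
W,8,D,median,847,85
W,8,D,p5,586,42
W,8,D,p25,722,63
W,8,D,p75,1060,120
W,8,D,p90,1368,167
W,8,D,kurtosis,2.19,0.031
W,8,D,skewness,0.034,0.0017
W,8,D,entropy,6.86,0.20
W,8,Dstar,mean,14944,791
W,8,Dstar,median,13004,787
W,8,Dstar,p5,4762,729
W,8,Dstar,p25,9429,655
W,8,Dstar,p75,18147,1104
W,8,Dstar,p90,25530,1683
W,8,Dstar,kurtosis,2.21,0.012
W,8,Dstar,skewness,0.0078,0.000038
W,8,Dstar,entropy,9.84,0.075
W,8,f,mean,11.0,0.80
W,8,f,median,9.00,0.50
W,8,f,p5,2.75,0.41
W,8,f,p25,6.50,0.50
W,8,f,p75,13.1,0.92
W,8,f,p90,20.3,2.69
W,8,f,kurtosis,2.07,0.036
W,8,f,skewness,0.19,0.029
W,8,f,entropy,3.60,0.070
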