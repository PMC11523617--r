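sample_id,garden_id,status,container_type,matter,color,temperature,salinity,ph,do_mg_l,redox,f,cl,no2,br,no3,po4,so4,na,nh4,k,mg,ca,gas_o2,gas_n2,ch4,co2,n2o,toc
ALST_C,ALST,C,Rainwater collector,Plastic,Blue,25.51,0.3,8.19,5.04,230,0.08,17.52,0.01,1.35,4.12,0,34.32,13.2,0.05,3.4,7.81,64.8,3.67,10.83,0.46,8966.9,1.67,7.65
ARK_C,ARK,C,Rainwater collector,Plastic,Blue,22.25,0.4,6.72,3.12,-64,0.16,16.48,0.03,0,0.05,0.93,3.26,6.19,3.09,125.24,11.18,39.99,0.31,5.22,9.04,28552.01,2.22,66
AVIA_C,AVIA,C,Rainwater collector,Plastic,Green,20.92,0,7.95,7.17,252,0.02,0.34,0.01,0.09,0.69,0.15,1.48,1,0.26,0.58,0.23,2.99,2.15,4.7,0.04,2038.17,0.2,3.2
BIG_C,BIG,C,Rainwater collector,Plastic,Blue,21.98,0,8.02,8.85,317,0.02,0.48,0.01,0.02,0.57,0.15,0.87,1.44,0,0.46,0.18,3.33,3,6.58,0.24,1192.21,0.22,2.51
BIL_C,BIL,C,Rainwater collector,Plastic,Blue,23.4,0,8.05,3.21,86,0.03,0.53,0.02,0.02,0.31,0.06,1.21,0.99,0.84,0.7,0.23,3.86,1.97,4.7,40.54,4233.84,0.54,6.33
BONN_C,BONN,C,Rainwater collector,Plastic,Blue,21.22,0,7.3,6.79,199,0.02,1.17,0.03,0.01,0.82,0.55,2.49,0.77,0.02,2.66,0.91,9.95,2.35,5.33,0.06,1735.24,0.13,31.65
COR_C,COR,C,Rainwater collector,Plastic,Blue,15.97,0.3,6.7,8.64,231,0.06,33.53,0.07,0,3.16,0,34.2,19.89,0,2.47,5.99,45.37,2.1,4.41,0.01,1809.48,0.05,32.97
DEC_C,DEC,C,Rainwater collector,Plastic,Blue,26.29,0.012,7.63,10.12,194,0.02,0.62,0.02,0.01,0.48,0.1,0.98,1.82,0.09,0.46,0.16,4.44,2.04,5.07,0.95,2967.18,0.02,3.05
EDF_C,EDF,C,Rainwater collector,Plastic,Blue,23.81,0,7.8,5.02,248,0.04,18.65,0.02,0,6,0.01,27.6,13.24,0,2.4,10.28,45.43,1.96,4.1,0.24,4611.83,0.05,3.77
ESP_C,ESP,C,Rainwater collector,Plastic,Blue,20.29,0,7.99,7.39,165,0.02,4.16,0.02,0.04,2.04,0.19,4.61,1.96,0,1.01,0.73,14.45,2.42,5.23,0.06,789.28,0.51,5.2
FOR_C,FOR,C,Rainwater collector,Plastic,Gray,23.71,0,7.85,5.75,296,0.01,0.23,0.01,0,0.4,0.09,0.79,0.86,0,0.19,0.12,2.46,2.2,4.93,0.23,1577.37,0.26,4.25
FRA_C,FRA,C,Watering can,Plastic,Green,18.13,0.1,5.7,10.07,264,0.11,3.32,0.07,0.01,0.08,0.24,3.94,1.01,0.39,21.46,3.97,26.81,1.91,5.08,0.14,1516.77,0.02,35.76
GAR_C,GAR,C,Rainwater collector,Plastic,Blue,18.45,0.3,7.97,6.82,160,0.05,29.23,0.05,0.04,3.6,0.79,28.99,5.51,0.12,8.26,4.33,72.61,1.78,4.51,0.25,6583.94,0.82,29.63
JUST_C,JUST,C,Rainwater collector,Plastic,Blue,20.83,0.1,7.67,6.91,260,0.05,4.21,0.06,0.02,12.04,3.41,12.95,6.86,0,16.66,2.37,32.71,1.91,4.68,0.12,3391.08,0.59,17.4
MID_C,MID,C,Rainwater collector,Plastic,Blue,20.43,0,7.28,4.56,284,0.02,0.25,0.01,0.05,0.64,0.06,1.24,0.74,0.08,0.32,0.2,5.63,2.46,5.55,0.24,1694.02,0.74,3
MOU_C,MOU,C,Rainwater collector,Plastic,Blue,23.68,0.3,7.79,7.02,237,0.07,62.57,0,0,3.32,0.07,65.65,29.4,0,1.82,8.23,75.23,2.24,4.96,0.02,4190.09,0.06,7.84
PER_C,PER,C,Rainwater collector,Plastic,Blue,21.5,0.1,7.26,1.95,71,0.07,0.59,0.07,0.02,0.12,0.45,0.92,1.08,0.09,2.49,0.83,19.95,2.34,5.71,1.48,4109.99,0.7,22.06
QUA_C,QUA,C,Rainwater collector,Plastic,Blue,21.86,0,7.17,5.09,254,0.02,0.37,0.02,0.01,0.82,1.15,0.98,0.42,0.18,5.14,0.35,2.65,2.12,4.76,0.3,2264.26,0.48,11.97
REB_C,REB,C,Rainwater collector,Plastic,Blue,21.21,0,5.72,8.32,328,0.02,0.41,0.01,0.01,0.7,0.24,0.63,0.68,0,0.24,0.11,1.89,2.11,4.37,0.04,731.88,0.01,2.14
RECU_C,RECU,C,Rainwater collector,Plastic,Blue,19.91,0.2,6.12,5.03,277,0.06,13.21,0.07,0,0.45,0.13,9.26,9.8,0,3.01,8.44,34.69,2.07,4.88,0.5,3726.21,0.48,21.39
SYT_C,SYT,C,Rainwater collector,Metal,Gray,23.24,0.2,7.63,4.11,207,0.07,19.25,0.03,0.02,1.73,0,29.7,13.3,0,6.2,4.03,37.31,2.11,4.81,0.18,977.73,3.01,15.12
TAS_C,TAS,C,Bucket,Plastic,White,16.21,0.2,7.78,7.55,256,0.06,10.81,0.04,0.52,0.5,0,30.44,8.8,0.91,3.31,6.36,34.97,1.95,4.4,0.21,2757.52,0.77,24.15
VOIL_C,VOIL,C,Rainwater collector,Plastic,White,25.97,0,8.76,9.23,199,0.04,1.42,0.02,0.01,0.07,0.33,1.16,2.29,0.11,0.86,0.34,5.27,1.91,4.66,0.5,1270.64,0.01,14.1
ALST_NC,ALST,NC,Rainwater collector,Plastic,Blue,25.17,0,8.49,3.48,49,0.01,0.32,0.02,0.03,0.13,0,1.28,0.85,0.57,0.61,0.24,4.87,2.11,5.02,18.74,2373.8,3.67,4.37
ARK_NC,ARK,NC,Rainwater collector,Plastic,Blue,19.09,0,7.93,8.6,190,0.03,0.22,0,2.6,0.01,0.07,0.46,1.2,0.02,0.58,0.15,2.92,2.08,4.65,0.17,770.9,0.14,1
AVIA_NC,AVIA,NC,Bucket,Plastic,Red,20.42,0,6.95,7.1,305,0.03,1.58,0.04,0.36,0.66,0.81,3.82,1.78,0.47,3.41,0.92,11.85,2.16,5.12,0.25,2071.3,2.74,7.9
BIG_NC,BIG,NC,Rainwater collector,Plastic,Blue,20.8,0,7.28,5.45,300,0.02,0.54,0.02,0.04,0.22,0.13,0.92,1.56,0.81,0.77,0.26,3.83,2.12,5.02,0.18,2065.25,0.5,5.77
BIL_NC,BIL,NC,Rainwater collector,Plastic,Blue,25.64,0.2,7.45,4.78,18,0.07,8.56,0.07,0.04,0.54,0.51,17.19,6.76,0,4.87,4.97,44.9,1.83,4.29,198.23,4200.24,0.73,11.61
BONN_NC,BONN,NC,Rainwater collector,Plastic,Green,22.18,0,7.27,7.46,283,0.04,0.38,0.01,0.01,0.02,0,0.88,0.8,0.03,0.39,0.24,5.29,1.87,4.42,0.04,5512.88,0.02,6.84
COR_NC,COR,NC,Rainwater collector,Plastic,White,14.95,0.3,7.35,8.51,250,0.11,31.27,0.05,0.1,2.24,0.36,33.15,20.66,0.41,5.52,6.3,62.76,1.77,5.55,0.24,2674.62,1.49,24.92
DEC_NC,DEC,NC,Rainwater collector,Plastic,Blue,28.09,0.3,7.29,6.74,265,0.04,25.65,0.02,0.02,10.33,0,18.31,15.21,0.02,3,6.21,65.03,2.12,4.97,0.12,11662.99,1.42,7.8
EDF_NC,EDF,NC,Rainwater collector,Plastic,Blue,26.38,0,7.99,2.64,105,0.02,0.28,0.01,0.13,0.21,0.07,0.58,0.41,0.29,0.55,0.22,4.38,2.01,4.35,1.01,2098.92,1.02,6.56
ESP_NC,ESP,NC,Rainwater collector,Plastic,Blue,20.13,0,8.28,6.91,188,0.02,0.18,0.03,0.01,0.13,0,0.43,0.53,0.02,0.12,0.4,9.57,6.45,21.22,0.37,365.14,0.49,3.18
FOR_NC,FOR,NC,Watering can,Plastic,White,21.3,0,6.15,6.6,285,0.02,0.82,0.02,0.1,0.48,0.63,1.32,1.75,0.09,1.49,0.38,4.55,2.07,5.22,0.14,1904.64,1.12,12.72
FRA_NC,FRA,NC,Rainwater collector,Plastic,Blue,17.7,0,6.98,7.86,245,0.24,42.46,0,1.86,0.02,0.64,22.82,26.91,0.4,14.85,8.46,38.82,1.58,7.44,15.9,4674.8,0.37,39.45
GAR_NC,GAR,NC,Rainwater collector,Plastic,Blue,17.7,0,7.98,9,206,0.03,0.73,0.03,0.03,1.83,1.61,2.38,1.26,0.24,6.1,1.16,10.42,2.85,6.43,0.22,1947.26,0.64,12.58
JUST_NC,JUST,NC,Rainwater collector,Plastic,Blue,20.23,0.1,7.59,3.28,70,0.09,1.23,0.05,0.4,0.79,0.3,2.82,1.55,0.93,4.38,0.62,16.65,2.09,4.57,11.23,2212.85,4.79,9.09
MID_NC,MID,NC,Rainwater collector,Plastic,Black,19.2,0.4,7.04,12.25,271,0.05,20.3,0.08,0,6.52,0.09,26.5,13.62,0.16,5.72,11.55,71.5,1.6,4.01,0.18,12075.54,1.6,5.5
MOU_NC,MOU,NC,Rainwater collector,Plastic,Gray,23.02,0,6.41,7.94,214,0.01,0.22,0.01,0.04,0.03,0,0.76,0.31,0,0.27,0.12,5.61,2.28,5.2,0.11,33.86,0.55,3.98
PER_NC,PER,NC,Rainwater collector,Plastic,Blue,21.8,0.1,7.64,3,257,0.04,2.04,0.05,0,0.56,0.52,2.9,1.37,0.03,3.01,0.68,18.66,2.12,4.8,0.18,1978.87,0,22.82
QUA_NC,QUA,NC,Rainwater collector,Plastic,White,24.93,0.1,7.44,6.56,192,0.18,12.09,0.03,0,0.02,0.06,33.61,8.72,0,2.93,6.59,24.46,1.97,4.65,0.17,417.37,0.28,14.52
REB_NC,REB,NC,Rainwater collector,Plastic,Blue,20.72,0.1,6.38,6.14,288,0.07,4.21,0.05,0.01,2.78,0.52,11.18,3.28,0.02,1.94,2.08,25.12,2.19,4.61,0.23,1358.77,0.01,5.12
RECU_NC,RECU,NC,Bucket,Plastic,White,17.01,0.2,6.58,6.42,254,0.11,11.41,0.07,0,0.1,0,16.36,9.72,0.15,2.08,7.41,38.73,2.2,5.15,1.24,3593.56,0.24,28.09
SYT_NC,SYT,NC,Rainwater collector,Metal,Gray,24.94,0.1,7.46,3.91,-158,0.1,7.33,0.02,0.01,0.02,0,8.83,5.54,1.7,4.13,4.26,29.31,0.69,4.67,69.23,12225.67,2.76,16.5
TAS_NC,TAS,NC,Bucket,Plastic,Black,14.82,0.1,8.17,5.96,228,0.06,3.15,0.08,0.21,0.33,0,9.36,3.43,0.43,1.02,2.13,23.81,1.95,5.56,0.36,2383.38,1.51,20.04
VOIL_NC,VOIL,NC,Rainwater collector,Plastic,Blue,29.12,0.2,8.05,5.83,245,0.07,11.08,0.05,0,0.45,0.87,30.65,7.8,0.04,6.04,5.06,48.95,2.11,5.08,1.52,3248.9,0.05,17.2
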