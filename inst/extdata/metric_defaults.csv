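metric,mean,sd,units,family
Vt_PET,13.59,7.65,cm^3,lognormal
Vt_MRI,11.41,10.09,cm^3,lognormal
ADC,0.00093,0.00014,mm^2/s,lognormal
D,0.00067,0.00013,mm^2/s,lognormal
Dstar,0.00902,0.0018,mm^2/s,lognormal
f,0.16,0.06,fraction,logitnormal
Ktrans,0.18,0.06,1/min,lognormal
ve,0.32,0.09,fraction,logitnormal
tau_i,0.67,0.15,s,lognormal
kep,0.5625,0.25,1/min,lognormal
SULmax,8.91,3.94,dimensionless,lognormal
SULmean,5.26,2.76,dimensionless,lognormal
K1,0.33,0.15,1/min,lognormal
k3max,0.0087,0.0049,1/min,lognormal
k3mean,0.0034,0.0021,1/min,lognormal
DV,0.89,0.14,dimensionless,lognormal
TBRmax,1.76,0.53,dimensionless,lognormal
TBRmean,1.29,0.27,dimensionless,lognormal
vb,0.05,0.02,fraction,logitnormal
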