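parameter,group,median,q1,q3,units
ADC_0_1000,low,1.26,1.07,1.34,1e-3 mm^2/s
ADC_0_1000,high,1.03,0.79,1.13,1e-3 mm^2/s
SPF,low,10.47,7.71,14.23,%
SPF,high,23.56,21.73,31.49,%
f,low,4.05,3.08,5.80,%
f,high,9.22,6.83,14.41,%
D,low,1.22,1.03,1.28,1e-3 mm^2/s
D,high,1.02,0.77,1.11,1e-3 mm^2/s
D_star,low,7.88,4.95,10.32,1e-3 mm^2/s
D_star,high,12.69,12.09,14.77,1e-3 mm^2/s
Ktrans,low,0.041,0.018,0.058,1/min
Ktrans,high,0.140,0.076,0.192,1/min
v_e,low,0.132,0.023,0.228,fraction
v_e,high,0.204,0.165,0.559,fraction
v_p,low,0.029,0.020,0.058,fraction
v_p,high,0.055,0.033,0.076,fraction
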