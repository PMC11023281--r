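subject_id,route,occasion,repeat_dosed,ka,ke,t_half,tmax,cmax,auc_0_24,auc_0_inf,auc_ratio,aumc_0_inf,mrt,vz_f,cl_f
K1,subcutaneous,1,0,5.729,0.144,4.823,0.5,15.02,124.53,128.87,0.97,961.38,7.460,0.810,0.116
K2,subcutaneous,1,0,1.588,0.123,5.616,1.0,19.61,160.49,170.15,0.90,1454.97,8.545,0.714,0.088
K3,oral,1,1,0.295,0.123,5.658,4.0,17.33,216.86,233.91,0.90,2569.71,10.986,0.523,0.064
K4,oral,1,1,0.691,0.120,5.788,4.0,16.10,198.07,213.79,0.90,2187.58,10.232,0.586,0.070
K5,oral,1,1,0.194,0.107,6.449,4.0,17.21,223.14,248.73,0.90,2964.55,11.919,0.561,0.060
K6,oral,1,1,0.225,0.142,4.889,4.0,20.25,178.11,186.40,0.96,1729.49,9.279,0.568,0.080
K7,oral,1,1,0.159,0.090,7.669,4.0,18.59,237.72,279.05,0.90,3894.82,14.957,0.595,0.054
K8,oral,1,1,0.323,0.129,5.363,4.0,14.30,158.52,168.66,0.90,1646.24,9.761,0.688,0.089
K2,oral,2,0,0.215,0.149,4.661,4.0,16.64,182.32,190.57,0.96,1813.98,9.513,0.593,0.076
K4,oral,2,0,0.175,0.128,5.423,8.0,13.66,183.55,197.90,0.90,2214.62,11.191,0.586,0.070
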