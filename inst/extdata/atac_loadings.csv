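scale,domain,item,correlated,specific,general
ia,neurodevelopmental,ia_1,0.80,0.20,0.78
ia,neurodevelopmental,ia_2,0.91,0.02,0.90
ia,neurodevelopmental,ia_3,0.86,0.19,0.85
ia,neurodevelopmental,ia_4,0.91,-0.13,0.91
ia,neurodevelopmental,ia_5,0.91,-0.09,0.91
ia,neurodevelopmental,ia_6,0.84,0.01,0.83
ia,neurodevelopmental,ia_7,0.77,0.61,0.69
ia,neurodevelopmental,ia_8,0.89,0.07,0.89
ia,neurodevelopmental,ia_9,0.79,0.57,0.70
hi,neurodevelopmental,hi_1,0.81,0.49,0.61
hi,neurodevelopmental,hi_2,0.84,0.40,0.68
hi,neurodevelopmental,hi_3,0.78,0.51,0.58
hi,neurodevelopmental,hi_4,0.88,0.53,0.68
hi,neurodevelopmental,hi_5,0.85,0.58,0.63
hi,neurodevelopmental,hi_6,0.69,0.59,0.45
hi,neurodevelopmental,hi_7,0.74,0.63,0.49
hi,neurodevelopmental,hi_8,0.88,0.63,0.62
hi,neurodevelopmental,hi_9,0.87,0.66,0.60
hi,neurodevelopmental,hi_10,0.80,0.37,0.66
asd,neurodevelopmental,asd_1,0.45,0.19,0.39
asd,neurodevelopmental,asd_2,0.75,0.34,0.64
asd,neurodevelopmental,asd_3,0.74,0.44,0.59
asd,neurodevelopmental,asd_4,0.59,0.45,0.42
asd,neurodevelopmental,asd_5,0.53,0.35,0.40
asd,neurodevelopmental,asd_6,0.80,0.25,0.72
asd,neurodevelopmental,asd_7,0.80,0.56,0.59
asd,neurodevelopmental,asd_8,0.86,0.64,0.62
asd,neurodevelopmental,asd_9,0.81,0.58,0.60
asd,neurodevelopmental,asd_10,0.78,0.58,0.56
asd,neurodevelopmental,asd_11,0.90,0.58,0.69
asd,neurodevelopmental,asd_12,0.77,0.25,0.68
asd,neurodevelopmental,asd_13,0.72,0.47,0.56
asd,neurodevelopmental,asd_14,0.76,0.59,0.54
asd,neurodevelopmental,asd_15,0.60,0.44,0.45
asd,neurodevelopmental,asd_16,0.78,0.60,0.56
asd,neurodevelopmental,asd_17,0.71,0.59,0.49
ld,neurodevelopmental,ld_1,0.74,0.51,0.61
ld,neurodevelopmental,ld_2,0.97,0.51,0.79
ld,neurodevelopmental,ld_3,0.83,0.48,0.68
odd,externalizing,odd_1,0.71,0.52,0.48
odd,externalizing,odd_2,0.84,0.64,0.56
odd,externalizing,odd_3,0.74,0.52,0.51
odd,externalizing,odd_4,0.86,0.64,0.57
odd,externalizing,odd_5,0.84,0.67,0.55
cd,externalizing,cd_1,0.75,0.65,0.46
cd,externalizing,cd_2,0.79,0.78,0.45
cd,externalizing,cd_3,0.80,0.48,0.56
cd,externalizing,cd_4,0.85,0.53,0.60
cd,externalizing,cd_5,0.46,0.29,0.32
dep,internalizing,dep_1,0.81,0.61,0.53
dep,internalizing,dep_2,0.56,0.55,0.32
dep,internalizing,dep_3,0.86,0.61,0.58
dep,internalizing,dep_4,0.82,0.64,0.53
dep,internalizing,dep_5,0.62,0.53,0.38
anx,internalizing,anx_1,1.00,0.66,0.61
anx,internalizing,anx_2,0.61,0.52,0.32
anx,internalizing,anx_3,0.68,0.63,0.34
anx,internalizing,anx_4,0.63,0.65,0.29
anx,internalizing,anx_5,0.63,0.73,0.24
anx,internalizing,anx_6,0.67,0.63,0.33
anx,internalizing,anx_7,0.73,0.59,0.40
anx,internalizing,anx_8,0.81,0.69,0.44
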