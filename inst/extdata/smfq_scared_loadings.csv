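scale,domain,item,correlated,specific,general
ia,neurodevelopmental,ia_1,0.77,0.25,0.73
ia,neurodevelopmental,ia_2,0.89,0.17,0.86
ia,neurodevelopmental,ia_3,0.84,0.30,0.79
ia,neurodevelopmental,ia_4,0.91,0.02,0.91
ia,neurodevelopmental,ia_5,0.92,0.06,0.91
ia,neurodevelopmental,ia_6,0.80,0.02,0.80
ia,neurodevelopmental,ia_7,0.78,0.69,0.62
ia,neurodevelopmental,ia_8,0.87,0.20,0.84
ia,neurodevelopmental,ia_9,0.79,0.64,0.63
hi,neurodevelopmental,hi_1,0.79,0.43,0.64
hi,neurodevelopmental,hi_2,0.82,0.37,0.68
hi,neurodevelopmental,hi_3,0.73,0.47,0.56
hi,neurodevelopmental,hi_4,0.89,0.45,0.72
hi,neurodevelopmental,hi_5,0.85,0.53,0.65
hi,neurodevelopmental,hi_6,0.65,0.56,0.43
hi,neurodevelopmental,hi_7,0.75,0.59,0.52
hi,neurodevelopmental,hi_8,0.87,0.63,0.62
hi,neurodevelopmental,hi_9,0.85,0.64,0.61
hi,neurodevelopmental,hi_10,0.79,0.34,0.66
asd,neurodevelopmental,asd_1,0.40,0.05,0.40
asd,neurodevelopmental,asd_2,0.78,0.39,0.66
asd,neurodevelopmental,asd_3,0.68,0.35,0.57
asd,neurodevelopmental,asd_4,0.64,0.38,0.51
asd,neurodevelopmental,asd_5,0.53,0.30,0.42
asd,neurodevelopmental,asd_6,0.75,0.10,0.73
asd,neurodevelopmental,asd_7,0.84,0.45,0.69
asd,neurodevelopmental,asd_8,0.86,0.53,0.68
asd,neurodevelopmental,asd_9,0.70,0.48,0.53
asd,neurodevelopmental,asd_10,0.74,0.46,0.58
asd,neurodevelopmental,asd_11,0.89,0.48,0.73
asd,neurodevelopmental,asd_12,0.66,0.22,0.60
asd,neurodevelopmental,asd_13,0.68,0.42,0.54
asd,neurodevelopmental,asd_14,0.78,0.67,0.52
asd,neurodevelopmental,asd_15,0.52,0.31,0.41
asd,neurodevelopmental,asd_16,0.77,0.62,0.53
asd,neurodevelopmental,asd_17,0.74,0.65,0.50
ld,neurodevelopmental,ld_1,0.75,0.50,0.62
ld,neurodevelopmental,ld_2,0.96,0.50,0.77
ld,neurodevelopmental,ld_3,0.80,0.53,0.66
odd,externalizing,odd_1,0.69,0.53,0.45
odd,externalizing,odd_2,0.77,0.62,0.49
odd,externalizing,odd_3,0.73,0.53,0.50
odd,externalizing,odd_4,0.84,0.63,0.56
odd,externalizing,odd_5,0.81,0.61,0.53
cd,externalizing,cd_1,0.72,0.62,0.44
cd,externalizing,cd_2,0.80,0.72,0.48
cd,externalizing,cd_3,0.78,0.50,0.54
cd,externalizing,cd_4,0.89,0.59,0.62
cd,externalizing,cd_5,0.48,0.36,0.32
smfq,internalizing,smfq_1,0.72,0.74,0.28
smfq,internalizing,smfq_2,0.64,0.59,0.30
smfq,internalizing,smfq_3,0.55,0.44,0.31
smfq,internalizing,smfq_4,0.78,0.34,0.60
smfq,internalizing,smfq_5,0.84,0.81,0.34
smfq,internalizing,smfq_6,0.74,0.76,0.28
smfq,internalizing,smfq_7,0.90,0.44,0.66
smfq,internalizing,smfq_8,0.85,0.80,0.36
smfq,internalizing,smfq_9,0.86,0.83,0.33
smfq,internalizing,smfq_10,0.77,0.69,0.38
smfq,internalizing,smfq_11,0.85,0.78,0.38
smfq,internalizing,smfq_12,0.84,0.76,0.40
smfq,internalizing,smfq_13,0.85,0.80,0.37
pd,internalizing,pd_1,0.73,0.72,0.26
pd,internalizing,pd_2,0.67,0.71,0.19
pd,internalizing,pd_3,0.92,0.66,0.51
pd,internalizing,pd_4,0.75,0.65,0.34
pd,internalizing,pd_5,0.56,0.51,0.23
pd,internalizing,pd_6,0.59,0.58,0.21
pd,internalizing,pd_7,0.88,0.83,0.34
pd,internalizing,pd_8,0.67,0.66,0.24
pd,internalizing,pd_9,0.71,0.75,0.21
gad,internalizing,gad_1,0.75,0.66,0.35
gad,internalizing,gad_2,0.77,0.72,0.32
gad,internalizing,gad_3,0.79,0.75,0.32
gad,internalizing,gad_4,0.82,0.76,0.34
gad,internalizing,gad_5,0.76,0.63,0.39
gad,internalizing,gad_6,0.89,0.68,0.51
gad,internalizing,gad_7,0.82,0.78,0.33
gad,internalizing,gad_8,0.78,0.74,0.32
gad,internalizing,gad_9,0.82,0.81,0.30
sad,internalizing,sad_1,0.64,0.65,0.18
sad,internalizing,sad_2,0.83,0.54,0.46
sad,internalizing,sad_3,0.70,0.63,0.26
sad,internalizing,sad_4,0.78,0.78,0.23
sad,internalizing,sad_5,0.68,0.68,0.21
sad,internalizing,sad_6,0.60,0.58,0.19
sad,internalizing,sad_7,0.64,0.66,0.17
sad,internalizing,sad_8,0.83,0.80,0.26
sa,internalizing,sa_1,0.58,0.50,0.29
sa,internalizing,sa_2,0.81,0.79,0.34
sa,internalizing,sa_3,0.95,0.84,0.46
sa,internalizing,sa_4,0.98,0.85,0.49
sp,internalizing,sp_1,0.82,0.77,0.26
sp,internalizing,sp_2,0.90,0.82,0.33
sp,internalizing,sp_3,0.87,0.86,0.23
sp,internalizing,sp_4,0.84,0.90,0.09
sp,internalizing,sp_5,0.77,0.61,0.37
sp,internalizing,sp_6,0.83,0.74,0.32
sp,internalizing,sp_7,0.81,0.85,0.09
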