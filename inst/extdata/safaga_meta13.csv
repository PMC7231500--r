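sample_id,site_id,latitude,longitude,depth_m,environment,n_specimens,berger_parker,evenness,mean_ppd
94-1-a,94-1,26.81417N,33.97683E,10,Sand between coral patches,901,0.17,0.54,0.67
94-1-b,94-1,26.81417N,33.97683E,10,Sand between coral patches,778,0.16,0.55,0.66
94-1-c,94-1,26.81417N,33.97683E,10,Sand between coral patches,785,0.18,0.53,0.66
94-1-d,94-1,26.81417N,33.97683E,10,Sand between coral patches,729,0.17,0.54,0.66
94-3-a,94-3,26.79117N,33.94667E,23,Muddy sand,510,0.45,0.41,0.74
94-3-b,94-3,26.79117N,33.94667E,23,Muddy sand,624,0.45,0.39,0.74
94-4-a,94-4,26.81417N,33.96533E,39,Mud,2140,0.22,0.50,0.83
94-4-b,94-4,26.81417N,33.96533E,39,Mud,1647,0.23,0.50,0.83
94-5,94-5,26.84733N,34.00483E,19,Reef slope,416,0.31,0.51,0.91
94-6,94-6,26.76750N,33.96283E,0.5,Mangrove channel,481,0.44,0.45,0.86
95-31,95-31,26.82933N,33.98483E,12,Reef slope,1187,0.49,0.43,0.85
B-5-8,B-5-8,26.82683N,33.95383E,6,Sandy seagrass,2161,0.43,0.47,0.68
C-1-3,C-1-3,26.83000N,33.98683E,40,Muddy sand with seagrass,3969,0.44,0.43,0.75
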