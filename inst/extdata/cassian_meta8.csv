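sample_id,latitude,longitude,depth_m,depth_rank,age_zone,environment,n_specimens,berger_parker,evenness,mean_ppd
Costalaresc,46.53995N,12.16390E,,-1,austriacum,reef basin,315,0.73,0.29,0.91
Lago Antorno,46.59438N,12.26100E,,-4.5,austriacum,reef basin,216,0.31,0.50,0.88
Misurina landslide,46.59490N,12.25962E,,-2,austriacum,reef basin,558,0.30,0.48,0.89
Picolbach,46.53427N,11.92253E,,4,aon,reef basin,213,0.28,0.54,0.92
Rumerlo cliff,46.53375N,12.09882E,,-4,aonoides,reef basin,229,0.22,0.54,0.91
Rumerlo ski slope,46.53684N,12.10214E,,-5,aonoides,back reef,33,0.21,0.58,0.93
Settsass,46.51733N,11.95846E,,2,aon,reef basin,296,0.24,0.50,0.91
Stuores,46.52872N,11.93672E,,-6,aon,reef basin,1026,0.33,0.53,0.95
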