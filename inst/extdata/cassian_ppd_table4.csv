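sample_id,Costalaresc,Lago Antorno,Misurina landslide,Picolbach,Rumerlo cliff,Rumerlo ski slope,Settsass,Stuores
Costalaresc,0,0.86,0.91,0.83,1.00,0.99,0.76,1.00
Lago Antorno,,0,0.52,0.93,0.94,1.00,0.95,0.95
Misurina landslide,,,0,1.00,0.94,0.96,0.96,0.95
Picolbach,,,,0,0.93,1.00,0.77,1.00
Rumerlo cliff,,,,,0,0.67,0.97,0.89
Rumerlo ski slope,,,,,,0,1.00,0.86
Settsass,,,,,,,0,0.97
Stuores,,,,,,,,0
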