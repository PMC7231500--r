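sample_id,94-1,94-3,94-4,94-5,94-6,95-31,B-5-8,C-1-3
94-1,0,0.97,1.00,1.00,0.86,0.83,0.70,0.91
94-3,,0,0.88,1.00,0.97,0.99,0.44,0.42
94-4,,,0,1.00,1.00,1.00,1.00,1.00
94-5,,,,0,1.00,0.89,1.00,1.00
94-6,,,,,0,0.96,0.86,0.97
95-31,,,,,,0,0.89,0.97
B-5-8,,,,,,,0,0.35
C-1-3,,,,,,,,0
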