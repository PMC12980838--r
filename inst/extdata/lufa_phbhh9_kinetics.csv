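soil,temperature_c,variant,k_per_day,se_k,p_k,lag_d,se_lag,p_lag,r_squared
LUFA 6S,5,PHBHH9,0.025,0.007,0.020,82,8,0.001,0.98
LUFA 6S,15,PHBHH9,0.020,0.002,0.0002,0,NA,0.58,0.97
LUFA 6S,20,PHBHH9,0.043,0.002,0.00001,0,NA,0.16,1.00
LUFA 6S,25,PHBHH9,0.11,0.02,0.004,13,1,0.001,0.99
LUFA 6S,30,PHBHH9,0.20,0.02,0.001,5,1,0.002,1.00
LUFA 6S,35,PHBHH9,0.22,0.01,0.00004,5,0,0.00004,1.00
LUFA 2.4,5,PHBHH9,0.011,0.005,0.069,164,128,0.004,0.93
LUFA 2.4,15,PHBHH9,0.025,0.008,0.034,74,10,0.002,0.96
LUFA 2.4,25,PHBHH9,0.081,0.024,0.026,24,4,0.002,0.96
LUFA 2.4,35,PHBHH9,0.088,0.003,0.00001,0,NA,1,1.00
LUFA 2.2,5,PHBHH9,0.0008,0.0001,0.002,0,NA,1,0.78
LUFA 2.2,15,PHBHH9,0.0045,0.0004,0.0002,0,NA,0.84,0.93
LUFA 2.2,25,PHBHH9,0.034,0.015,0.080,31,13,0.076,0.95
LUFA 2.2,35,PHBHH9,0.096,0.029,0.028,14,4,0.016,0.97
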