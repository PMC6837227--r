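factor,substrate,block_id,slope,intercept,r_squared
H_plus,VA,1,0.07,0.98,0.96
H_plus,VA,2,0.07,0.96,0.96
H_plus,VA,3,0.06,0.93,0.95
H_plus,VE,1,0.06,1.66,0.92
H_plus,VE,2,0.06,1.64,0.92
H_plus,VE,3,0.06,1.61,0.91
ClO2,VA,1,0.94,1.61,0.96
ClO2,VA,2,0.94,1.56,0.96
ClO2,VA,3,0.93,1.48,0.96
ClO2,VE,1,0.87,2.20,0.97
ClO2,VE,2,0.85,2.13,0.98
ClO2,VE,3,0.82,2.04,0.98
substrate,VA,1,0.33,1.03,0.91
substrate,VA,2,0.35,1.01,0.93
substrate,VA,3,0.39,0.98,0.94
substrate,VE,1,0.30,1.82,0.91
substrate,VE,2,0.30,1.80,0.91
substrate,VE,3,0.29,1.77,0.91
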