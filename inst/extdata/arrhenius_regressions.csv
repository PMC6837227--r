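substrate,block_id,slope_K,intercept,r_squared
VA,1,-899.55,4.87,0.98
VA,2,-849.89,4.70,0.97
VA,3,-795.92,4.52,0.94
VE,1,-14.70,4.67,0.97
VE,2,-14.54,4.65,0.96
VE,3,-14.37,4.62,0.95
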