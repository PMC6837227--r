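substrate,block_id,inv_T_e3,log_k,flag
VA,1,2.92,2.24,
VA,1,2.99,2.21,printed_x_inconsistent
VA,1,3.00,2.16,
VA,1,3.05,2.14,
VA,1,3.10,2.07,
VA,2,2.92,2.22,
VA,2,2.96,2.19,
VA,2,3.00,2.14,
VA,2,3.05,2.13,
VA,2,3.10,2.06,
VA,3,2.92,2.19,
VA,3,2.96,2.17,
VA,3,3.00,2.12,
VA,3,3.05,2.11,
VA,3,3.10,2.04,
VE,1,2.92,2.79,
VE,1,2.99,2.78,printed_x_inconsistent
VE,1,3.00,2.76,
VE,1,3.05,2.74,
VE,1,3.10,2.71,
VE,2,2.92,2.77,
VE,2,2.96,2.76,
VE,2,3.00,2.74,
VE,2,3.05,2.72,
VE,2,3.10,2.69,
VE,3,2.92,2.74,
VE,3,2.96,2.74,
VE,3,3.00,2.71,
VE,3,3.05,2.69,
VE,3,3.10,2.66,
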