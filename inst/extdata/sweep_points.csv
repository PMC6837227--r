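factor,substrate,block_id,log_level,log_rate
H_plus,VA,1,-4.00,0.70
H_plus,VA,1,-3.50,0.76
H_plus,VA,1,-3.00,0.77
H_plus,VA,1,-2.50,0.82
H_plus,VA,1,-2.00,0.84
H_plus,VA,2,-4.00,0.67
H_plus,VA,2,-3.50,0.74
H_plus,VA,2,-3.00,0.75
H_plus,VA,2,-2.50,0.80
H_plus,VA,2,-2.00,0.82
H_plus,VA,3,-4.00,0.67
H_plus,VA,3,-3.50,0.72
H_plus,VA,3,-3.00,0.73
H_plus,VA,3,-2.50,0.78
H_plus,VA,3,-2.00,0.80
H_plus,VE,1,-4.00,1.40
H_plus,VE,1,-3.50,1.47
H_plus,VE,1,-3.00,1.48
H_plus,VE,1,-2.50,1.51
H_plus,VE,1,-2.00,1.53
H_plus,VE,2,-4.00,1.38
H_plus,VE,2,-3.50,1.44
H_plus,VE,2,-3.00,1.45
H_plus,VE,2,-2.50,1.49
H_plus,VE,2,-2.00,1.51
H_plus,VE,3,-4.00,1.35
H_plus,VE,3,-3.50,1.42
H_plus,VE,3,-3.00,1.43
H_plus,VE,3,-2.50,1.46
H_plus,VE,3,-2.00,1.48
ClO2,VA,1,-1.61,0.10
ClO2,VA,1,-1.30,0.34
ClO2,VA,1,-1.13,0.62
ClO2,VA,1,-1.00,0.60
ClO2,VA,1,-0.91,0.77
ClO2,VA,2,-1.61,0.06
ClO2,VA,2,-1.30,0.30
ClO2,VA,2,-1.13,0.57
ClO2,VA,2,-1.00,0.56
ClO2,VA,2,-0.91,0.73
ClO2,VA,3,-1.61,-0.01
ClO2,VA,3,-1.30,0.23
ClO2,VA,3,-1.13,0.50
ClO2,VA,3,-1.00,0.48
ClO2,VA,3,-0.91,0.65
ClO2,VE,1,-1.61,0.79
ClO2,VE,1,-1.30,1.07
ClO2,VE,1,-1.13,1.28
ClO2,VE,1,-1.00,1.29
ClO2,VE,1,-0.91,1.40
ClO2,VE,2,-1.61,0.75
ClO2,VE,2,-1.30,1.02
ClO2,VE,2,-1.13,1.22
ClO2,VE,2,-1.00,1.24
ClO2,VE,2,-0.91,1.35
ClO2,VE,3,-1.61,0.70
ClO2,VE,3,-1.30,0.97
ClO2,VE,3,-1.13,1.15
ClO2,VE,3,-1.00,1.17
ClO2,VE,3,-0.91,1.28
substrate,VA,1,-1.51,0.52
substrate,VA,1,-1.33,0.59
substrate,VA,1,-1.21,0.65
substrate,VA,1,-1.11,0.68
substrate,VA,1,-1.03,0.66
substrate,VA,2,-1.51,0.46
substrate,VA,2,-1.33,0.54
substrate,VA,2,-1.21,0.60
substrate,VA,2,-1.11,0.63
substrate,VA,2,-1.03,0.61
substrate,VA,3,-1.51,0.39
substrate,VA,3,-1.33,0.47
substrate,VA,3,-1.21,0.53
substrate,VA,3,-1.11,0.57
substrate,VA,3,-1.03,0.56
substrate,VE,1,-1.51,1.35
substrate,VE,1,-1.33,1.45
substrate,VE,1,-1.21,1.48
substrate,VE,1,-1.11,1.48
substrate,VE,1,-1.03,1.50
substrate,VE,2,-1.51,1.33
substrate,VE,2,-1.33,1.42
substrate,VE,2,-1.21,1.45
substrate,VE,2,-1.11,1.46
substrate,VE,2,-1.03,1.48
substrate,VE,3,-1.51,1.31
substrate,VE,3,-1.33,1.40
substrate,VE,3,-1.21,1.43
substrate,VE,3,-1.11,1.43
substrate,VE,3,-1.03,1.46
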