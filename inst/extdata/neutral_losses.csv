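loss,formula,mass_da,classes
H2O,H2O,18.010565,MFA;DFA;CAD
CO2,CO2,43.989830,MFA;DFA;CAD
HCOOH,CH2O2,46.005480,MFA;DFA;CAD
H2O+CO2,CH2O3,62.000395,MFA;DFA
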