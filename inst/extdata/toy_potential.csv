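atom_class,epsilon,sigma,charge
C,0.11,3.4,0.0
CPOS,0.11,3.4,0.25
N,0.17,3.25,-0.4
O,0.21,3.0,-0.5
HPOL,0.046,1.0,0.35
S,0.25,3.55,-0.1
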