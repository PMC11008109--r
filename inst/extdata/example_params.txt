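# Dye reversibly binding a macromolecule, intermediate-rate regime
# (dimensionless parameter set; tau_B sets the unit of time)
tau_ratio = 0.1666667
beta = 0.5
v = 1
omega = 5
tau_B = 2.1e-05
N1 = 0.2
N23 = 1
Q_B = 1
Q_C = 1.3
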