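# 2-state 3-mode linear-vibronic-coupling model of pyrazine
# (S1 n-pi* / S2 pi-pi* internal conversion; the standard literature
# parameter set). Modes: nu1, nu6a (tuning), nu10a (coupling).
# All energies in eV; converted to hartree on load. Dimensionless
# mass-weighted normal-mode convention (mode mass = 1/omega).
model: lvc
units:
  energy: eV
modes: [nu1, nu6a, nu10a]
omega:  [0.1258, 0.0739, 0.1139]
E:      [3.94, 4.84]
kappa1: [0.0470, -0.0964, 0.0]
kappa2: [0.2012, 0.1194, 0.0]
lambda: [0.0, 0.0, 0.1825]
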