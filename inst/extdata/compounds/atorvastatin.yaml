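# Atorvastatin (calcium) compound file.
# CYP3A4 intrinsic clearance was retrograde-calculated from oral clearance
# assuming fa = 1, fg = 0.24; P-gp kinetics from Caco-2 with an estimated
# relative activity factor.  Peff and Vss are parameter-estimated values.
name: atorvastatin
ionization_class: monoprotic_acid
mw: 588.2
logp: 5.7
pka: [4.46]
fu: 0.051
bp_ratio: 0.61
vss: 4.78           # L/kg, parameter estimated
clpo: 949
clpo_units: L/h
clpo_basis: plasma
clpo_note: "unit tag normalized to L/h"
clint_3a4: 8.28     # uL/min/pmol CYP3A4
peff: 6.12e-4       # cm/s, parameter estimated
jmax_pgp: 151       # pmol/cm^2/min
km_pgp: 115         # uM
raf_pgp: 8.7
fa_assumed: 1.0
fg_assumed: 0.24
dose_mg: 10
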