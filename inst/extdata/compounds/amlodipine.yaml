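# Amlodipine (besylate) compound file.
# Peff and Vss are the parameter-estimated values; CLpo unit tag is L/h
# (the source table's L/min is not physiological for a 25 L/h-class drug).
name: amlodipine
ionization_class: diprotic_base
mw: 408.88
logp: 3.43
pka: [9.4, 1.90]
fu: 0.07
bp_ratio: 1.0
vss: 13.78          # L/kg, parameter estimated
clpo: 24.8
clpo_units: L/h
clpo_basis: plasma
clpo_note: "unit tag normalized to L/h"
clint_3a4: ~        # not a quantified CYP3A4 substrate; hepatic CL lumped
peff: 1.35e-4       # cm/s, parameter estimated
jmax_pgp: ~
km_pgp: ~
raf_pgp: ~
fa_assumed: 0.90    # from its own absorption simulation (fasted single)
fg_assumed: 1.0     # no gut-wall metabolism modeled
dose_mg: 5
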