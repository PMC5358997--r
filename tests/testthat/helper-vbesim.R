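# shared fixtures: bundled compound presets and a linear (no CYP, no P-gp)
# probe compound for limiting-case checks
amlo <- preset_compound("amlodipine")
ator <- preset_compound("atorvastatin")

linear_compound <- function(peff = 2e-4, vss = 10) {
  compound_profile("probe", "neutral", mw = 400, fu = 0.5, bp_ratio = 1,
                   vss = vss, clpo = 20, clpo_units = "L/h",
                   peff = peff, fa_assumed = 1, fg_assumed = 1, dose_mg = 10)
}

# independent CAT oracle: closed-form absorbing-cascade fraction absorbed for
# instant release with first-order transit and absorption (no metabolism)
cat_cascade_fa <- function(kge, kt, ka, ktc, ka_colon) {
  reach <- 1   # all of the dissolved dose empties from the stomach
  fa <- 0
  for (i in seq_along(kt)) {
    fa <- fa + reach * ka[i] / (ka[i] + kt[i])
    reach <- reach * kt[i] / (ka[i] + kt[i])
  }
  fa + reach * ka_colon / (ka_colon + ktc)
}
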