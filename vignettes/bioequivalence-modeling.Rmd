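---
title: "From dissolution vessels to virtual trials: the models behind vbesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dissolution vessels to virtual trials: the models behind vbesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbesim)
```

## What the package models

`vbesim` assesses whether two immediate-release oral formulations — here a
fixed-dose combination (FDC) orally disintegrating tablet of amlodipine
(5 mg) and atorvastatin (10 mg) versus the single-drug tablets — can be
expected to behave the same in vivo.  It works at three levels:

1. **In vitro dissolution**: profiles are compared with the FDA difference
   and similarity factors,
   $f_1 = 100\,\sum_t |R_t - T_t| \big/ \sum_t R_t$ and
   $f_2 = 50\,\log_{10}\!\big(100 / \sqrt{1 + \tfrac1n \sum_t (R_t-T_t)^2}\big)$,
   with the biowaiver rule that comparison is unnecessary when both products
   release more than 85% of dose within 15 minutes.  Profiles are declared
   similar when $f_1 < 15$ and $f_2 > 50$.
2. **In vitro permeability**: Caco-2 monolayer transport is summarized as
   the apparent permeability $P_\mathrm{app} = (dQ/dt)/(C_0 A)$ and the
   efflux ratio $P_\mathrm{app}^{B\to A}/P_\mathrm{app}^{A\to B}$, with TEER
   for monolayer integrity and a donor/receiver/withdrawn-sample mass
   balance.
3. **In silico absorption and trials**: a compartmental absorption and
   transit (CAT-type) gut model with gut-wall CYP3A4 metabolism and
   saturable P-glycoprotein efflux feeds a minimal PBPK disposition model;
   virtual populations turn this into trial-level statements about AUC,
   $C_\mathrm{max}$ and $t_\mathrm{max}$, and the oral bioavailability
   decomposition $F_\mathrm{oral} = f_a \times f_g \times f_h$ explains
   *why* exposures differ.

Every input the pipeline consumes can be produced by seeded synthetic
generators with known ground truth, so each analysis stage is testable as a
round trip.

## Dissolution handling

Dissolution testing withdraws an aliquot (5 mL from a 900 mL vessel) at
each sampling time and replaces it with fresh medium; measured
concentrations therefore under-report cumulative release.
`correct_cumulative()` applies
$M_n = C_n V + v_s \sum_{i<n} C_i$ before any comparison.

`f1_factor()`/`f2_factor()` evaluate the statistics on replicate means (the
source data are reported as mean ± SD, n = 3).  Because the statistics are
grid-sensitive, mismatched time grids are an error — there is no silent
interpolation.  By default at most one common point after both profiles
exceed 85% dissolved is included, the usual regulatory convention; the
truncation is configurable off.

Release curves are summarized by a Weibull model
$F(t) = F_\infty\,(1 - e^{-(t/t_d)^\beta})$ (first-order release is the
$\beta = 1$ special case; a tabulated pass-through with monotone
interpolation is also available).  The bundled presets reproduce the eight
measured plateaus: amlodipine 94.9% (FaSSIF single), 101.2% (FaSSIF FDC),
87.9% / 79.9% (FeSSIF); atorvastatin 80.0% / 89.3% (FaSSIF), 76.9% / 86.2%
(FeSSIF).  The sources report plateaus but not time constants, so the time
scales are package choices, fixed once: FaSSIF kinetics are fast (4 min for
amlodipine, which exceeds 50% release by 5 min and 85% by 15 min; 6 min for
atorvastatin); FeSSIF kinetics are slower (25 / 18 min for amlodipine,
consistent with neither fed-state product reaching 85% within 15 min, and
60 min for atorvastatin).  The atorvastatin fed-state value encodes the
physics of a weak acid (pKa 4.46): the ionized — soluble — fraction at
FeSSIF pH 5.0 is roughly 25-fold lower than at FaSSIF pH 6.5, partly offset
by bile-salt solubilization, i.e. an order-of-magnitude slowdown.

## Caco-2 analysis

`apparent_permeability()` regresses the withdrawal-corrected cumulative
receiver mass on time over a linear window.  The default window is the
sink-condition region (cumulative transfer below 10% of the initial donor
mass), falling back to the best-$r^2$ contiguous window of at least four
points.  The slope is fit through the origin with $1/t^2$ weights —
equivalently the mean per-point transfer rate — because chromatographic
assay error is multiplicative (constant CV), and an unweighted fit lets the
noisiest late points dominate: in simulation at 5% assay CV the weighted
estimator recovers $P_\mathrm{app}$ with ~1.2% median error where
unweighted variants sit at 2.5–3.5%.  The unweighted $r^2$ is still
reported as a linearity diagnostic and estimates with $r^2 < 0.9$ are
flagged.

## The gut model

The gut is a stomach, seven small-intestinal segments (duodenum, jejunum
I–II, ileum I–IV) and a colon.  Solid and dissolved drug transit with
first-order rates; the seven equal small-intestinal rates give a mean
transit of 3.3 h (the standard CAT convention).  Gastric emptying is
first-order with half-life 0.25 h fasted and 1.0 h fed.  Absorption from
each segment is permeability-limited, $k_a = 2 P_\mathrm{eff}/r$, into an
enterocyte compartment that loses drug to CYP3A4 metabolism
(`CLint,3A4 ×` segmental abundance `×` unbound concentration, enterocyte
unbound fraction 1), to apical P-gp efflux back to the lumen
(Michaelis–Menten, $RAF \cdot w_i \cdot J_\mathrm{max} A_i\, C/(K_m + C)$),
and to portal blood via segmental villous flow (total 18 L/h, distributed
by surface area).  The colon absorbs (at one tenth of the
surface-normalized rate, radius 2.5 cm) but does not metabolize.
A total small-intestinal CYP3A4 abundance of 66.2 nmol and hepatic
abundance of 9.0 µmol are the system defaults; with the atorvastatin
compound file these make the retrograde intrinsic-clearance calculation
(below) self-consistent with the tabulated 8.28 µL/min/pmol to within a few
percent.

**Release in vivo.** The luminal release rate is driven by the *shape* of
the fitted in vitro profile through its hazard
$h(t) = f'(t)/(1-f(t))$ with $f = F/F_\infty$ (for Weibull release simply
$h(t) = (\beta/t_d)(t/t_d)^{\beta-1}$, capped at 10 min⁻¹).  The in vitro
plateau is treated as an assay recovery/equilibrium limit rather than a cap
on in vivo release: the full dose remains releasable.  The decisive
observation is that the simulated fasted fraction absorbed for atorvastatin
is the same (0.91) for both the single product (in vitro plateau 80.0%) and
the FDC (89.3%) — in vivo absorption evidently exceeds the in vitro
plateau, so capping release at the plateau would be wrong.  A corollary is
that two formulations differing only in plateau produce identical
simulations; differences must come through kinetics, which matches the
trial-level finding that single and FDC products are bioequivalent.

**The stomach is not a dissolution vessel.** FaSSIF/FeSSIF emulate
intestinal fluid, so applying their release kinetics to the stomach would
let an acid pre-dissolve where it is in fact least soluble.  The gastric
hazard is therefore scaled by the ionization-driven solubility ratio
$S(\mathrm{pH_{stomach}})/S(\mathrm{pH_{medium}})$ with
$S \propto 1/f_\mathrm{unionized}$: atorvastatin (acid) essentially does
not dissolve in the fasted stomach (scale ≈ 0.009), while amlodipine (base)
dissolves immediately there (scale capped).  This is compound-driven — no
per-state tuning knob.

**Regional CYP3A4.** Expression is greatest duodenally and declines ab
orally.  The default abundance weights halve per segment
(normalized $2^{0}, 2^{-1}, \dots, 2^{-6}$).  A linear 7:1 decline was
evaluated first but makes the proximal-to-distal extraction contrast too
shallow to express the fed-state mechanism at the plasma level (the
fed/fasted $C_\mathrm{max}$ ratio inverts); the steep profile is consistent
with reported order-of-magnitude proximal-to-distal CYP3A protein
gradients, and the weights are user-overridable (any strictly decreasing
profile is accepted).  P-gp weights increase linearly ab orally.

With these pieces the fed-state food effect for atorvastatin emerges
mechanistically rather than by assumption: slower fed-state release and
gastric emptying leave solid drug transiting the lumen, dissolution
completes more distally, absorption shifts toward ileal segments and colon
where CYP3A4 abundance is low, the fraction metabolized in the gut falls
(0.75 fasted → 0.60 fed in the deterministic run), $f_g$ rises
(0.25 → 0.39), and fed AUC and $C_\mathrm{max}$ exceed fasted despite the
slower absorption.  Amlodipine, which has no quantified gut metabolism,
shows only the gastric-emptying effect: a later $t_\mathrm{max}$ when fed.

Mass conservation (dose = unreleased + luminal + enterocyte + metabolized +
portal + exited colon) is checked on every simulation; the solver runs at
relative tolerance 1e-8 / absolute 1e-10 and the deviation is at the
1e-15 level.  Negative states beyond −1e-9 are an error, as is solver
failure (reported with the failure time).

## Compound-level algebra

Ionization follows Henderson–Hasselbalch for the declared class (the
diprotic base uses both pKa values).  The unbound blood fraction is
$fu_b = fu/\,(B{:}P)$.  Hepatic extraction uses the well-stirred model
$CL_h = Q_h\, fu_b\, CL_{u,\mathrm{int}} / (Q_h + fu_b\, CL_{u,\mathrm{int}})$.
Under that model the retrograde calculation — recovering intrinsic
clearance from in vivo oral clearance — is closed-form:
$CL_{u,\mathrm{int}} = CL_{po}^\mathrm{blood}\, f_a f_g / fu_b$
(the flow terms cancel), and it is property-tested as the exact inverse of
the forward chain.  Atorvastatin's hepatic clearance is mechanistic
(CLint,3A4 × hepatic abundance); amlodipine, whose compound file carries no
CYP-specific intrinsic clearance, uses a lumped clearance back-calculated
from its oral clearance with $f_a = 0.90$, $f_g = 1$.  The tabulated oral
clearances (24.8 and 949) are carried with an explicit unit tag read as
L/h — as printed in L/min they would be two to three orders of magnitude
above hepatic blood flow.  Two tabulated estimate pairs
($P_\mathrm{eff}$ 1.35×10⁻⁴ / 6.12×10⁻⁴ cm/s; $V_{ss}$ 13.78 / 4.78 L/kg)
have a grammatically ambiguous drug assignment in the source; the presets
pair 1.35×10⁻⁴ cm/s and 13.78 L/kg with amlodipine, which matches the
literature magnitudes of both drugs (flagged here, as the other reading
cannot be excluded).

## Disposition and trials

The minimal PBPK model is a well-stirred liver (volume 1 L, blood flow
97 L/h) in series with one central compartment of volume
$V_{ss} \times$ body weight; portal input enters the liver, giving dynamic
first-pass extraction, and plasma concentration is central blood
concentration divided by the B:P ratio.  A one-peripheral-compartment
extension was deliberately not added: the compound files carry a single
$V_{ss}$.  Population variability is exchangeable log-normal multipliers
with arithmetic mean 1 — CV 30% on clearance and $V_{ss}$, 40% on gut and
liver CYP3A4 abundance (simulator population libraries do not print these;
the values are typical of healthy-volunteer PK).  Trials of 50 subjects per
arm over 24 h, sampled every 15 min, are the default study size; paired
fed/fasted comparisons reuse the same population seed so mechanism
contrasts are not drowned by between-subject noise.  Cmax is summarized as
geometric mean (geometric SD), AUC (linear trapezoid) and tmax as median
(range).  Group comparison uses the unpaired two-tailed t test (Welch by
default) on untransformed parameters, with the geometric-mean ratio and
90% CI as a bioequivalence-style diagnostic.

Parameter estimation (`estimate_parameters()`) is bounded multi-start
weighted least squares on the log parameter scale (L-BFGS-B).  The
recommended weighting for plasma concentrations is $1/y^2$, which matches
multiplicative assay error; with it, $P_\mathrm{eff}$ and $V_{ss}$ are
recovered from clean synthetic data to well under 1% and from 10%-noise,
12-subject pooled data to well under 10% median error.

## What the synthetic generators do and do not emulate

The generators produce Weibull dissolution curves with additive Gaussian
sampling noise truncated at zero (assay-like), sink-regime transport runs
whose recorded concentrations exactly invert the withdrawal correction,
mean-1 log-normal populations, and plasma tables from the forward simulator
with multiplicative residual error — each under a named, reproducible seed
stream.  They do not emulate: non-sink transport (donor depletion
curvature), inter-vessel hydrodynamic differences, supersaturation or
precipitation, enterohepatic recirculation, metabolite kinetics, or
digitization error of literature profiles.  Passing round-trip tests
therefore demonstrates internal consistency of the estimators under the
stated error model, not robustness to every artifact of real data.  In
particular, reproducing the published replicate-level f1/f2 values for the
real tablets requires the study's deposited dissolution data (which has no
named accession); the package reproduces the decision logic exactly and the
generated presets land close to, but not at, the published statistics.

## Numerical choices and limitations

* Solvers: `deSolve::lsoda`; tolerances 1e-8/1e-10 for absorption results,
  1e-6/1e-9 inside population loops and optimization (speed); the
  acceptance analyses use 50-subject arms, 100-seed recovery studies and a
  20-seed estimation study.
* Release hazard capped at 10 min⁻¹; sub-first-order shapes ($\beta < 1$)
  are singular at $t = 0$ and take the cap there.
* Ties in $t_\mathrm{max}$ resolve to the first time reaching the maximum;
  an all-zero profile reports $C_\mathrm{max} = 0$ with flagged
  $t_\mathrm{max}$.
* Degenerate inputs: zero dose yields an identically zero profile; zero
  permeability yields $f_a = 0$ with zero portal flow; $f_g$ is reported as
  1 when nothing is absorbed.
* Known limitations: no pH-dependent solubility mechanics in the intestine
  (release is profile-driven by design), no bile-micelle partitioning, no
  OATP uptake or atorvastatin metabolites, no drug–drug interaction between
  the two APIs (the FDC acts through its dissolution profile; an optional
  Peff scaling by the combination/single Papp ratio exists and is off by
  default), and absolute exposure magnitudes depend on system parameters
  (enzyme abundances, villous flow) that published tables do not pin down —
  the package's trial-level claims are therefore directional contrasts, not
  absolute predictions.
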