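---
title: "Methods: simulating and analyzing exoenzyme robustness in a nine-member community"
author: "commrobust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing exoenzyme robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commrobust)
```

## The study design

A nine-member community of drinking-water isolates is grown statically
for 72 h in every leave-one-out configuration: each member alone
(monocultures), all nine together (the full mix), and all nine
eight-member dropouts, every member inoculated at OD600 = 0.05 (full
mix ≈ 0.45 total). Cell-free supernatants are assayed for four secreted
activities — short-chain lipase (NPB), long-chain lipase (NPP),
choline-specific phospholipase C (NPPC) and protease (FITC-casein) —
and community composition is enumerated by differential plating.
Functional robustness has an operational definition here: an activity
is robust when no dropout community differs significantly from the full
mix in a family-wise many-to-one comparison.

`buildDesigns()` enumerates the 2N+1 designs in a fixed order (mix,
dropouts, monocultures). `interactionCapacity()` and
`kSubsetInteractions()` give the combinatorial context for a nine-member
community: 502 possible multi-member interaction sets, 120 restricted
to pairs and triples.

## Assay model and units

Nitrophenyl substrates release nitrophenol measured at 410 nm; the
Beer–Lambert conversion with ε = 17,700 M⁻¹cm⁻¹ turns a
blank-corrected absorbance delta into molar product, reported
canonically as nmol/ml/min/OD600. Two unit choices deserve note:

- **Path length** is not a property of the chemistry but of the plate
  well; it is a required constant defaulting to 1.0 cm and is the
  dominant systematic unknown when comparing absolute scales between
  instruments. All conversions are bit-reproducible given the constant.
- The field often reports mass-based "PLC units" (ng/ml/min/OD600)
  without stating whose mass; this package treats them as nitrophenol
  mass equivalents (nmol × MW 139.11), exposed only as derived views
  of the molar canonical unit. Absolute cross-study scale comparison is
  therefore explicitly out of scope.

Protease activity is a baseline-subtracted fluorescence rate
(RFU/h/OD600) using each sample's own t = 0 autofluorescence, and
percent liposome lysis is linear normalization between a heat-killed
negative control (0%) and Triton X-100 (100%), reported unclipped with
an out-of-range flag. Small negative blank-corrected signals are
routine assay noise and clip to zero with a warning rather than
erroring.

## The synthetic world

No replicate-level raw data exist for this system, so the generator is
a first-class module whose defaults *are* the study's stated
conditions. Its parameters were fixed from printed summaries before any
downstream test was run:

- **Endpoint composition.** Proportions are fitness × interaction
  modifiers, lognormally perturbed and renormalized. Fitness weights
  equal the measured −Cg endpoint proportions and *C. gleum*'s
  presence-modifiers equal the ratio of the measured full-mix to −Cg
  proportions, so at zero noise the simulated full-mix and −Cg
  communities reproduce the measured compositions *exactly* (including
  Cg ≈ 27.7% and the release of B. cepacia from 11% to 28% when Cg is
  absent). Interaction effects are presence/absence multipliers — the
  simplest structure able to encode the release effect; no
  density dependence, no growth dynamics.
- **Noise.** Activities receive multiplicative lognormal noise
  (CV 0.2, the rough proportionality seen in monoculture error bars);
  per-well compositions receive lognormal perturbation (CV 0.1,
  matching the ~8–20% relative SDs of the plating table); colony
  counts are multinomial draws of equal plated aliquots (900 countable
  colonies at full growth). Every replicate is simulated as its own
  well with its own composition, so composition variability enters the
  within-group variance instead of biasing whole designs.
- **Community activity mixing rule.** How nine species' intrinsic
  activities combine in co-culture is genuinely unknown — the study's
  own point is that simple summation fails. The rule is therefore
  pluggable with three built-ins. `proportional_sum` is the plain
  abundance-weighted mean of monoculture activities;
  `regulated_mean` multiplies it by a per-enzyme regulation factor
  ≤ 1. The default, `regulated_setpoint`, encodes the study's
  conclusion that feedback regulation sets secretion to a level
  appropriate to the environment: every mixture settles at the
  full-community level times the regulation factor, independent of
  which single member is absent. The one non-robust interaction is
  carried by an actor-specific regulation modifier: C. gleum, while
  present, halves the NPPC factor (0.7 → 0.35), so its removal roughly
  doubles community NPPC hydrolysis — deliberately more than the
  accompanying compositional rise of the NPPC producers can explain,
  which is exactly the pattern the real community showed. Default
  factors are NPB 0.9, NPP 0.85, NPPC 0.7 (×0.5 with Cg), protease
  0.6; monocultures always express their intrinsic activity, since
  they are the reference the null model is built from.
- **What a green test does not establish.** The generator emulates
  endpoint summaries, not mechanism: no spatial biofilm structure, no
  quorum-sensing dynamics, no density-dependent interactions, no
  kinetic curves. Tests passing on this world validate the *pipeline*
  (conversions, deconvolution, statistics, classification), not any
  biological claim about the real community.

## Differential plating and deconvolution

The packaged growth matrix records −/+/++ growth for each species on
unsupplemented LB, carbenicillin, cetrimide, trimethoprim, gentamicin
and kanamycin at 30 and 37 °C, plus PIA at 37 °C; untested
combinations are NA and raise on use. Colony appearance contributes a
second signature axis (C. gleum orange, R. insidiosa rough-edged,
everything else white/beige). Slow growth (+) is scored as no growth by
default — the conservative reading of "less than half of colony size" —
with a flag to include it.

Two subtleties surfaced while encoding the matrix:

1. *Identifiability is signature distinctness,* and the published
   narrative scheme (total counts, gentamicin, trimethoprim, colony
   classes) leaves C. metallidurans and B. multivorans with identical
   strict signatures; cetrimide (or PIA) at 37 °C, on which only
   B. multivorans grows, separates them.
2. *Signature distinctness does not imply solvability of the count
   system.* Counts couple species additively within (condition, colony
   class) cells; even an identifiable scheme can be rank-deficient
   (with the scheme above, Rp/Cm/Ss/Bc remain entangled). The default
   scheme therefore adds kanamycin at 37 °C, whose only normal growers
   are Cm and Cg, restoring full rank; `resolveComposition()`
   additionally verifies rank and refuses otherwise.

Deconvolution models each observed cell count as the sum of
plated-volume-scaled abundances of the species in that cell — which
requires plates to be equal aliquots of the same sample, and is why the
simulator draws a plate as a multinomial over growers *plus an
unobserved no-growth bin* rather than renormalizing each plate to a
fixed total. The system is solved by ordinary least squares (unbiased)
with a Lawson–Hanson non-negative fallback when counting noise drives
a rare species below zero; a deficit beyond five standard deviations of
the largest plate total is instead reported as inconsistent counts.
Standard errors are multinomial, √(p(1−p)/n) at the largest plate
total; the published table's parenthetical values are replicate SDs, a
different quantity, and the two are reported side by side but never
compared numerically.

## Diversity indices

Shannon H (natural log, zeros dropped), Simpson λ = Σp² with Gini and
inverse variants, richness as detected species, and Pielou J = H/ln S.
Inputs are renormalized before computation because printed percentage
columns carry rounding error (they sum to ~99.8). From the measured
full-mix composition these give H = 1.92 and J = 0.87, matching the
published values; J = 0.77 also reproduces from the published
H = 1.61 with S = 8. Two published numbers do *not* reproduce from the
published composition under any standard variant — Simpson 0.34 / 0.46
(the table gives λ ≈ 0.17 / 0.20) and the −Cg Shannon 1.61 (the table
gives 1.75) — and are documented here rather than silently adjusted;
no test asserts them.

## The null model

Expected mixture activity is computed from monoculture activities Aᵢ
(means across replicates) and member proportions pᵢ under two
conventions, both first-class because the study's stated arithmetic —
"divide each monoculture activity by its fractional proportion and
sum" — yields E = ΣAᵢ/pᵢ, which inflates the prediction by n² for an
even mixture and may or may not be intended. `literal_divide` is the
default because it is the stated operation; `proportional_sum`
(E = ΣAᵢpᵢ, always between min and max Aᵢ) is the conservative
alternative; every output row records which was used, and no numeric
conclusion in this package depends on the choice. Weights are either
exact input fractions (1/9, 1/8) or resolved endpoint proportions with
zeros dropped and the remainder renormalized. Differences are reported
as actual − expected, negative meaning the community under-produces
relative to prediction — as every mixture does for NPPC under both
conventions, in the data and in the default simulation.

## Statistics

Dunnett's many-to-one procedure is implemented directly: the
comparisons of k dropouts against the shared full-mix reference are
jointly multivariate t with correlation λᵢλⱼ, λᵢ = √(nᵢ/(nᵢ+n₀)).
That one-factor structure collapses the k-variate orthant probability
to a double integral (reference deviate × pooled scale) evaluated by
adaptive quadrature — deterministic, no Monte-Carlo, accurate to well
below 1e-4 (tests verify against a large-sample Monte-Carlo oracle, and
k = 1 reduces exactly to the pooled t-test). Replicates from three
experiments × three wells are pooled (n = 9), as the figure legends
imply; experiment is not modeled as a factor. The composition
comparison uses the two-way species × condition layout with per-species
contrasts on the pooled residual variance and Sidak adjustment
1−(1−p)^m over the m species; proportions enter untransformed by
default since no transform is stated. Tier symbols follow the study's
convention (* p<0.05, ** p<0.01, # p<0.001).

Degenerate inputs are refused, not patched: zero within-group variance
(as in exact zero-noise simulations) makes variance-based comparisons
undefined, and `runStudy()` then reports empty statistics tables rather
than inventing p-values.

## Numerical choices and limitations

- Zero-noise limits are exact by construction (lognormal factor ≡ 1 at
  CV 0, expected plate counts available via `exactCounts`), which is
  what makes parameter-recovery tests sharp.
- All randomness flows from one seed per run through local RNG scopes;
  identical seeds give byte-identical output bundles.
- The robustness verdict is a family-wise significance statement at
  α = 0.05 per enzyme. On a fully robust truth it still has the nominal
  ~5% per-enzyme chance of flagging some dropout; the packaged default
  seed is simply one realization, and the FWER calibration test checks
  the 5% is honest, not absent.
- "Robust" here is absence of evidence of change, not equivalence
  testing; no TOST, no mixed models, no mechanistic regulation model —
  the pipeline quantifies discrepancy, it does not explain it.
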