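---
title: "Assessing the arrhythmogenic capacity of fibrotic atrial substrate"
author: "atrialRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the arrhythmogenic capacity of fibrotic atrial substrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atrialRD)
```

## What this package models

Atrial fibrosis remodels both the cardiomyocyte membrane and the tissue it
sits in, and the joint effect can turn an atrium into a substrate that
sustains reentrant drivers (RDs, "rotors") — the engines of many atrial
fibrillation episodes. `atrialRD` implements the full in-silico workflow
used to interrogate that substrate: a human atrial ionic model with
remodeling variants, a monodomain tissue solver on (bi)layer triangulated
surfaces, a synthetic fibrotic-substrate generator, a clinical rapid-pacing
induction protocol, phase-based rotor detection with region-wise
inducibility scoring, fibrosis density/entropy pattern analysis with a
pro-RD classifier, and cohort-level statistics.

## The membrane model and its remodeling variants

Cell-scale kinetics follow the Courtemanche–Ramirez–Nattel human atrial
action-potential model (21 state variables; fast Na⁺, transient-outward,
ultrarapid/rapid/slow delayed-rectifier K⁺, inward-rectifier, L-type Ca²⁺
currents, pumps, exchanger, and a two-compartment sarcoplasmic reticulum).
Electrical remodeling enters purely as multiplicative conductance scalings:

* **afib** — AFib-remodeled: I_Kur ×0.5, I_to ×0.5, I_CaL ×0.3, fitted in
  the source literature to clinical monophasic action potentials;
* **fibrotic** — applied *on top of* the AFib scalings: I_CaL ×0.5 (net
  0.15 of baseline), I_Na ×0.6, I_K1 ×0.5, representing TGF-β1-driven
  remodeling in fibrotic tissue.

```{r}
rc <- remodelingContrast(bcl = 500)
rc$apdIncreasePct        # ~ +16 % APD90, fibrotic vs afib
rc$upstrokeReductionPct  # ~ -47 % max ionic dV/dt
```

Two measurement conventions matter here and are deliberate design choices:

* **Upstroke velocity** is the maximum *ionic* rate of rise, i.e. the
  applied stimulus current is subtracted before taking the maximum. With
  current-injection pacing the raw trace derivative contains the stimulus
  amplitude itself (≈ +22 mV/ms at twice diastolic threshold), which
  dilutes any between-variant contrast; the ionic definition makes the
  metric independent of the pacing amplitude.
* **"Paced to limit cycle"** is operationalized as successive-beat APD90
  change < 0.1 ms (cap 200 beats). The fibrotic variant has no true limit
  cycle at BCL 500 ms: halving I_K1 leaves the cell with a slow, unbounded
  depolarizing drift (resting potential −75 → −52 mV over thousands of
  beats, by which point it is barely excitable). The physiologically
  meaningful state is the early quasi-stationary plateau, which the APD
  criterion selects (beats 3–5) and where the resting-potential elevation
  (≈ 8 % vs the AFib variant) matches the values reported for this model
  pair in the source literature. When the two variants are compared
  (`remodelingContrast()`), both are paced for the same number of beats —
  the later of the two convergence points — so the contrast is evaluated
  on a common pacing history.

Integration is Rush–Larsen for the twelve voltage-dependent gates (with
voltage-indexed lookup tables at 0.02 mV resolution), forward Euler for
concentrations; the default cell-scale step of 12.5 µs was chosen so that
APD90 agrees with a classical RK4 reference at 5 µs within 0.5 ms for all
three variants. Stimulus charge is booked as a K⁺ influx in the
intracellular potassium balance (charge-conservative pacing). The models
deliberately lack calcium-driven afterdepolarizations; no ectopic
automaticity is modeled anywhere in the package.

## Tissue model

Propagation obeys the monodomain equation
β C_m ∂V/∂t = ∇·(σ∇V) − β(I_ion − I_stim), discretized with linear
triangular finite elements (lumped mass) and first-order operator
splitting (reaction, then explicit diffusion). Conductivities (S/m) are
σ_L = 0.409 / σ_T = 0.0820 in non-fibrotic tissue (5:1 anisotropy) and
σ_L = 0.177 / σ_T = 0.0221 in fibrotic tissue (8:1), with per-element
tensors σ_T I + (σ_L − σ_T) f fᵀ along the element fiber direction.
Defaults C_m = 1 µF/cm², β = 0.14 µm⁻¹ give a voltage diffusivity
D = σ/(10 β C_m) in mm²/ms. Nested endocardial/epicardial shells are
built by duplicating a surface 100 µm along its vertex normals; interlayer
links (σ = 0.8 S/m) are treated as pairwise exchanges and relaxed exactly
each step (unconditionally stable regardless of the link rate). The link
cross-section is each node's lumped (Voronoi) area, which cancels against
the lumped mass so the exchange rate is simply σ_link/(10 β C_m L²).

Numerical behavior worth knowing:

* Activation is an upward crossing of −10 mV.
* The explicit diffusion step requires dt below h²/(2 tr D); the solver
  caps dt at 0.05 ms and the tissue default is 0.025 ms.
* CV converges first-order in dt (≈ 3 % change when halving from 25 µs);
  spatial discretization *slows* propagation as h approaches the wavefront
  width, which hits the slow fibrotic transverse direction first: at
  200–400 µm a fully fibrotic transverse wave blocks decrementally, while
  at 50 µm it propagates at ≈ 16 cm/s. This resolution-dependent block at
  tissue-grade resolutions mirrors the conduction block that fibrosis
  produces physiologically, but it is a numerical property and is treated
  as such throughout.
* At the 200 µm reference resolution the solver yields ≈ 87 cm/s
  longitudinally and ≈ 36 cm/s transversely for the non-fibrotic
  conductivities. The transverse value matches the published effective CV
  (37.14 cm/s) within 4 %; the longitudinal one is ≈ 21 % above the
  published 71.49 cm/s. Those two published values have ratio 1.93, which
  is inconsistent with a 5:1 conductivity ratio in any convergent
  monodomain discretization (√5 ≈ 2.24); they originate from earlier
  volumetric models at coarser resolution, where numerical slowing is
  large. We keep the stated parameters rather than introducing
  per-direction correction factors, and report the discrepancy openly.

## Synthetic substrates

Patient imaging data are not available, so substrates are synthetic and
fully parameterized by a `SubstrateSpec` (geometry, resolution, target
burden, texture correlation length, patchiness, seed); every output is a
pure function of (spec, seed).

* **Geometry.** Flat sheets (structured triangulations) and an idealized
  left-atrium shell: an ellipsoid with four pulmonary-vein ostia, an open
  appendage tip and the mitral cap removed — six boundary loops — with
  longitude/latitude surrogate coordinates standing in for anatomical
  coordinates.
* **Fibrosis.** White noise per element, graph-diffusion smoothed to the
  requested correlation length, mixed with a fine-grained component
  (weight 1 − patchiness), thresholded at the area-weighted quantile that
  delivers the target burden (achieved burden within one element's area of
  the target; unbiased across seeds). Bilayer shells share one pattern.
  Default burden 14 % reflects the imaging cohorts this emulates
  (13.6–14.2 % means); the texture defaults (correlation length 1.5 mm,
  patchiness 0.85) produce patchy fibrosis with interdigitated boundaries,
  the morphology the density/entropy analysis targets.
* **Regions.** The left/right PV regions are grown from the ostium rims to
  15 % of total surface area each; the remainder splits into floor,
  posterior and anterior+appendage by coordinate cutoffs.
* **Pacing sites.** Fifteen: anterior/posterior aspects of all four PV
  ostia, appendage base, mitral annulus, posterior wall, plus four
  distributed wall/floor sites; the left-PV region holds exactly four.
  The mapping of the four unnamed sites is a surrogate convention and is
  recorded in the output metadata.
* **Fibers.** Rule-based: circumferential around ostia and the mitral rim,
  blending into an oblique (30°) wall direction; sheets take uniform
  angles, optionally different per layer.

What the generator does *not* emulate: wall-thickness variation, imaging
noise, anatomically realistic fiber atlases, and the centimetre-scale
fibrotic confluence of real atria. Tests that pass on these substrates
validate the machinery, not clinical fidelity.

## Induction protocol and outcome classification

Each attempt delivers 12 stimuli: two pulses 300 ms apart, couplings
ramping 280 → 200 ms in 20 ms steps, then 200 ms held so the train totals
12 (the unique completion consistent with the protocol's endpoints; last
onset at 2500 ms). Tissue starts from cell states paced to limit cycle at
BCL 500 ms; stimulus amplitude defaults to twice the tissue capture
threshold found by bisection. Activity is self-sustaining while any
activation occurs in every successive 500 ms window; episodes sustained
5000 ms past the last stimulus are classified by phase analysis:
persistent phase singularities → RD; otherwise consistent phase winding
around an interior boundary loop (vein ostium, mitral rim) → macroscopic
reentry, which is excluded from all driver statistics. When both
signatures coexist the RD call takes precedence and the record is flagged.

Phase is the argument of the analytic signal of the mean-subtracted
voltage (500 ms sliding mean removal); singularities are triangles whose
boundary phase winds by ±2π, linked frame-to-frame within 2 mm, with
trajectories shorter than one rotation discarded. Unique morphologies are
single-linkage clusters of trajectory mean positions at 10 mm; the merge
radius is roughly half a region's linear scale. Region-wise inducibility
scores divide RD inductions from a region's sites (summed over a cohort)
by the region's site count; the raw numerator is reported alongside.

## Fibrosis pattern metrics

FD(e) is the area-weighted fibrotic fraction within a 2.5 mm geodesic
ball around element e (graph distances between element centroids); FE(e)
is the binary entropy of the fraction of discordant edge-adjacent label
pairs inside the ball. The pair-discordance definition keeps FE from
collapsing into a function of FD: a solid patch and a finely interleaved
mixture can have the same FD but very different FE. The pro-RD rule is the
published support-vector-machine boundary, evaluated exactly as printed
(0.4096 FD² + 3.28 FD FE − 0.1036 FE² − 0.7112 FD − FE + 0.0429), with
"positive value" as the pro-RD side (the high-density/high-entropy corner
evaluates to +1.92) and an FD > 0.01 guard neutralizing the +0.0429
constant at zero density. The quiescent analysis pools final voltages of
1000 ms stimulus-free runs across models, takes the 95th percentile
(linear interpolation) as the abnormal-depolarization threshold, and
reports each model's fraction above it; the threshold is cohort-derived,
never a constant.

## The virtual cohort and its honest limits

`runVirtualCohort()` generates one substrate per model (burden swept
uniformly over a range, seeds derived from a master seed), runs the full
induction/analysis stack per pacing site, and summarizes per model.
Statistics follow the published battery: Wilcoxon rank-sum with
Hodges–Lehmann 95 % intervals for continuous contrasts, χ² (Yates
correction, the base-R 2×2 default, which reproduces the published
inducibility comparison) for categorical ones, and product-moment
correlation plus a logistic fit — both reported, since the source
describes logistic regression while printing R values.

The reduced-scale defaults (20 models, 20–32 mm sheets at 400 µm, 1–3
pacing sites, 5000 ms observation) keep one induction around 10–60 s of
desktop compute. A hard physical limitation follows from the membrane
model: the AFib-remodeled wavelength (CV × APD ≈ 5–7 cm along fibers)
cannot close a reentrant circuit inside such domains, and scaling
conductivities down to shrink the wavelength pushes the slow transverse
direction below the discrete propagation threshold at any affordable
resolution. Rapid pacing on these sheets therefore produces wavebreak and
transient reentry (up to a few hundred ms) but not 5000 ms sustained
drivers; sustained inducibility at the published rates requires
atrial-scale (~10 cm) domains. The cohort machinery, rotor analysis and
statistics are exercised and verified on analytic rotor fixtures and
miniature cohorts instead; the sustained-inducibility cohort experiment
should be run at full scale on appropriate hardware via the same API
(`cohortSpec(sheetSize = 100, nSites = 15, ...)`).

## Reproducibility

Every generator and the solver are deterministic given (configuration,
seed); cohort runs are bit-reproducible from the master seed, and each
output directory written by the CLI carries its resolved configuration
and seeds.
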