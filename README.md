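# atrialRD

In-silico assessment of the arrhythmogenic capacity of fibrotic left-atrial
substrate. `atrialRD` is aimed at computational cardiac electrophysiologists
who want a self-contained, scriptable version of the fibrotic-substrate
interrogation workflow: build a (synthetic) atrial tissue model with a
patient-like fibrosis pattern, provoke it with a clinical rapid-pacing
sequence, and quantify whether, where, and why reentrant drivers (RDs)
take hold.

## What is inside

* **Membrane model** — the Courtemanche–Ramirez–Nattel human atrial action
  potential with AFib-remodeled (I_Kur, I_to −50 %, I_CaL −70 %) and
  fibrotic-remodeled (additionally I_CaL −50 %, I_Na −40 %, I_K1 −50 %)
  variants; Rush–Larsen integration with an RK4 reference path.
* **Tissue solver** — monodomain reaction–diffusion,
  β C_m ∂V/∂t = ∇·(σ∇V) − β(I_ion − I_stim), linear triangular finite
  elements with anisotropic fiber tensors (healthy 0.409/0.082 S/m,
  fibrotic 0.177/0.0221 S/m), bilayer shells joined by interlayer links.
* **Synthetic substrates** — idealized left-atrium shells (4 PV ostia,
  appendage, mitral rim; five anatomical regions; 15 trigger-site pacing
  locations) and sheets, with seeded thresholded-random-field fibrosis of
  controllable burden and texture.
* **Induction & rotor analysis** — the 12-stimulus ramp protocol
  (300 → 200 ms couplings), 5000 ms sustainment criterion, Hilbert-phase
  singularity detection and tracking, RD vs macroscopic-reentry
  classification, unique-morphology counting, region-wise inducibility
  scores (IdS).
* **Fibrosis pattern metrics** — local fibrosis density and entropy, the
  published pro-RD classification polynomial, region-wise pro-RD burden,
  and the quiescent resting-voltage (pro-trigger) analysis.
* **Cohort pipeline** — burden-swept virtual cohorts with the published
  statistical battery (rank-sum, χ², correlation/logistic fits).

## Worked example

```r
library(atrialRD)

# cell-scale remodeling contrast at BCL 500 ms
rc <- remodelingContrast(bcl = 500)
rc$apdIncreasePct
#> [1] 16.17905
rc$upstrokeReductionPct
#> [1] 46.77559
```

The fibrotic-remodeled cell prolongs its APD90 by ≈ 16 % and slows its
maximum (ionic) upstroke by ≈ 47 % relative to the AFib-remodeled cell —
the cell-scale signature that, at tissue scale, slows and destabilizes
conduction through fibrotic regions.

```r
# a fibrotic sheet, its pattern metrics, and one induction attempt
spec <- substrateSpec("sheet", c(20, 20), resolution = 400,
                      fibrosisBurden = 0.2, correlationLength = 2,
                      seed = 11)
mesh <- generateSubstrate(spec)
mesh
#> BilayerMesh: 2601 nodes, 5000 triangles, 0 interlayer links
#>   layers: 1; fibrotic burden: 20.0% of surface area
#>   regions: 1

met <- localFibrosisMetrics(mesh, radius = 2.5)
met
#> FibrosisMetricsMap: 5000 elements, radius 2.50 mm
#>   FD mean 0.198, FE mean 0.294, pro-RD fraction 0.153

co  <- meshNodes(mesh)
rec <- runInduction(mesh, which((co[,1] - 2)^2 + (co[,2] - 10)^2 < 1),
                    amplitude = 100, model = "demo", site = "left")
rec
#> InducibilityRecord demo @ left: none (sustained 60.95 ms, 0 RD events)
```

On a 20 mm sheet the ramp captures and, beyond a brief post-pacing
transient, the waves extinguish — sustained reentrant
circuits of this membrane model need atrial-scale domains (see the
vignette's discussion of wavelength); the same call against a full-scale
mesh is how the substrate of a real-sized atrium is interrogated.

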