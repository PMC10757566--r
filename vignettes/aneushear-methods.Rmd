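---
title: "Methods: wall-shear postprocessing, outlet tuning and paired inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall-shear postprocessing, outlet tuning and paired inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneushear)
```

`aneushear` covers the analysis that sits downstream of a 3D
hemodynamic solve of a cerebral aneurysm: outlet boundary-condition
construction and tuning, reduction of the wall-shear-stress (WSS)
field to dome metrics, mesh-convergence bookkeeping, and matched-pair
inference. This vignette records the models, the numerical choices,
and the design decisions that were genuinely open — and what the
synthetic-data tests do and do not demonstrate about real data.

## Units

Internal units are CGS throughout: cm, g, s, dyne, barye
(dyne/cm²). mmHg and mm appear only at interfaces, with
1 mmHg = 1333.22 barye. Blood defaults to density 1.06 g/cm³ and
viscosity 0.04 Poise, the standard Newtonian approximation for
cerebral CFD.

## The lumped outlet model

Each outlet is a 3-element Windkessel. The package adopts the
standard closure

$$C \frac{dP_c}{dt} = Q(t) - \frac{P_c - P_\mathrm{ref}}{R_d},
\qquad P(t) = P_c + R_p\,Q(t),$$

with the proximal fraction fixed at $R_p/(R_p+R_d) = 0.1$ (a 1:9
proximal:distal split) unless overridden. The distal reference
pressure defaults to $P_\mathrm{ref} = 0$; it is configurable because
venous back-pressure conventions differ between groups.

Resistance is distributed over outlets inversely to outlet area,
$R_i = R_\mathrm{total} A_\mathrm{total}/A_i$, which preserves the
parallel total identically and represents physiological flow splits
in the cerebral circulation better than Murray's law. For global
pressure tuning the outlets are collapsed to their parallel
equivalent with a single lumped capacitance; the tuned capacitance is
redistributed per outlet proportionally to $1/R_i$. This reduction is
exact for the tuned quantities (limit-cycle inlet-equivalent
pressures) because all branches share the proximal fraction and
reference pressure; it is *not* a claim about per-branch transients.
The 120/80 mmHg targets are applied at the lumped inlet-equivalent
node, the only pressure node a 0D surrogate has.

**Integration.** The ODE is linear but potentially stiff for small
$R_d C$; `simulate_rcr()` uses `deSolve::lsoda` with a maximum
internal step of period/200 and reads systolic/diastolic from dense
output sampled at period/400 (user-adjustable down to period/200, the
contract bound). A fixed-step RK4 oracle at 10× finer steps agrees
with the adaptive trace to 0.1% on systolic/diastolic in the test
suite.

**Limit cycle.** A trace is converged when both systolic and
diastolic change by at most 5% between the last two cycles. Inside
the tuner a stricter 0.5% cycle-to-cycle criterion is used so that
the pressures fed back into the iteration are genuinely periodic;
starting the capacitor at the steady mean-flow pressure
$P_\mathrm{ref} + \bar{Q} R_d$ makes this take only a handful of
cycles.

**Tuning.** The two targets decouple naturally: the cycle-mean
pressure depends (exactly, by integrating the ODE over one cycle) on
$\bar{Q} (R_p + R_d) + P_\mathrm{ref}$ and not on $C$, while the
pulse pressure is governed by $C$ through the impedance
$|R_p + R_d/(1 + i\omega R_d C)|$. `tune_rcr()` therefore sets
$R_\mathrm{total}$ from the mean estimate
$(P_\mathrm{sys} + 2 P_\mathrm{dia})/3$, runs a secant iteration on
$C$ against pulse pressure, and re-enters the resistance stage on the
residual mean error. The iteration aims for a fifth of the user
tolerance (default tolerance 5%, so an internal 1%) so the returned
set sits comfortably inside the acceptance band rather than on its
edge; every evaluation is appended to an audit log. A constant
inflow is rejected up front — no capacitance can create pulse
pressure that the forcing does not contain.

## Shear metrics

Per point, with $T$ the cycle period,

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\mathbf{w}(t)|\,dt, \qquad
\mathrm{OSI} = \frac{1}{2}\left(1 -
\frac{|\int_0^T \mathbf{w}\,dt|}{\int_0^T |\mathbf{w}|\,dt}\right),$$

by trapezoidal integration on the stored, possibly non-uniform time
grid whose last sample must close the cycle. OSI is defined as 0
where the magnitude integral vanishes, and clamped into $[0, 0.5]$
at rounding scale only.

Regional summaries are **area-weighted**: the per-triangle value is
the mean of its three vertex values, the per-triangle region the
majority vote of vertex labels (full ties go to the parent vessel),
and the regional mean is $\sum a_c v_c / \sum a_c$ over region
triangles with cross-product areas. Whether spatial means in this
field are area-weighted or plain vertex averages is usually left
unstated; area weighting was chosen because it is
triangulation-invariant — on strongly graded meshes a vertex average
over-weights refined patches. Minima and maxima are taken over region
points. Excluded-label points (reserved for a manually clipped
impingement zone) contribute to no region.

Low-shear areas use strict `<` at the threshold: ties count as not
low, a measure-zero convention on continuous fields that makes the
two-level synthetic construction below exact. The LSA threshold is
parent mean − 1 (area-weighted, population) spatial SD; a negative
threshold yields LSA = 0.

## The synthetic generator

The generator replaces imaging-derived geometry and the 3D solve; it
emulates only the *statistical and geometric structure* the
downstream analysis consumes, not flow physics.

* **Geometry**: an open straight tube (parent, default radius 0.2 cm,
  length 2 cm) plus a hemispherical dome (default radius 0.35 cm)
  seated on its wall; edge size controls resolution and is refused if
  it exceeds the dome radius. The dome and tube are separate labeled
  patches ("watertight-enough": the analysis needs areas and labels,
  not a closed volume).
* **Parent field**: a smooth axial sinusoid around the Poiseuille
  anchor $\tau = 4\mu Q/(\pi R^3)$ with amplitude $\sqrt 2\,
  \mathrm{CV}$ (so CV < 1/√2 keeps it positive), phase drawn from the
  seed. Smoothness, not noise, supplies heterogeneity — per-point
  noise would not be stable under mesh refinement, and refinement
  stability is one of the invariants under test.
* **Two-level dome**: an exact fraction `dome_low_fraction` of dome
  area is set to `dome_low_level` × the realized parent mean, the
  rest exactly to the parent mean. Exactness is achieved by walking
  the dome triangles pole-outward, splitting the single straddling
  triangle at the exact area parameter (sub-triangle area is linear
  in the split parameter), and duplicating seam vertices so every
  dome triangle is purely low or purely normal. This makes MTLSA
  ground truth exact by triangle bookkeeping — e.g. a 30% low patch
  gives MTLSA_70 = 30.00 exactly — at the cost of a hanging node and
  a split seam, both irrelevant to area-weighted metrics.
* **Exact OSI**: every dome point keeps constant shear magnitude
  while its direction follows the schedule
  $0,\dots,0,+\theta,-\theta,\pi,\dots,\pi$ on the uniform time grid.
  Under trapezoidal integration the magnitude integral is exactly
  $\tau T$ and the vector integral has magnitude $\tau h (b +
  2\cos\theta)$ with $b$ an integer set by the flip position — so the
  flip index and $\theta$ are solved in closed form from the target
  OSI, which is then reproduced exactly (targets below $1/(2n)$ on an
  $n$-interval grid are unrepresentable and rejected). Parent points
  keep a fixed direction (OSI 0).
* **Waveform**: a truncated Fourier series (decaying harmonics with
  increasing phase lead: fast systolic upstroke, slow diastolic
  runoff), discretely renormalized so the sampled cycle mean and
  pulsatility index are *exact*. Published cerebral waveforms are
  figures, not tables, so the shape is parametric rather than a
  digitization; the default mean flow of 4 cm³/s and PI 1.0 are
  representative ICA values.
* **Cohorts**: stable members are a literature-scale baseline (typical
  stable-aneurysm dome summaries) plus Gaussian noise; growing members equal their stable partner plus
  independent noise plus an additive effect on one named metric; all
  metrics are clipped to valid ranges (TAWSS ≥ 0, OSI ∈ [0, 0.5],
  areas ∈ [0, 100]%). Defaults: 11 pairs, per-metric noise SDs of
  ~25 percentage points on area fractions and comparable literature-scale
  values elsewhere. Clipping can attenuate differences
  for baselines near a bound; the null-calibration test shows the
  exact test's size survives this at the default settings.

Because construction and measurement share the triangle bookkeeping
(areas, vertex-mean values), ground-truth recovery to 1e-10 validates
the *metrics pipeline's* integration and weighting — the independent
checks are the analytic limits (constant field, reversing sinusoid,
Poiseuille) and the dense-resampling and enumeration oracles in the
test suite. What passing these tests does **not** show: fidelity of
any CFD solution, behavior on irregular clinical geometry, or metrics
under secondary-flow direction fields richer than the two-direction
schedule.

## Mesh convergence

`check_converged()` declares convergence at the first refinement
whose dome-mean TAWSS is within 5% of the *previous* refinement
(the protocol's stopping rule); the reporting residual
(TAWSS − final)/final and normalized size (edge/final edge) are also
emitted, since published refinement figures use the final-mesh
denominator while the stopping rule uses the previous-step one. Both
conventions are in the output table so the ambiguity is explicit.
The module consumes (edge size, metric) pairs; it does not remesh.

## Paired inference

The cohort test is the Wilcoxon **signed-rank** test on paired
growing-minus-stable differences — the only paired Wilcoxon test,
though reports in this literature sometimes call it a "paired rank
sum" test. Zero differences are dropped before ranking (Wilcoxon's
treatment; Pratt's is available via `zero_method = "pratt"`), tied
magnitudes get mid-ranks, and for n ≤ 20 the two-sided p-value is
exact: the distribution of W over all $2^n$ sign assignments is built
by dynamic programming over doubled ranks (integers even with
mid-rank ties), and p is the symmetric tail mass
$P(|W - M/2| \ge |w - M/2|)$. Beyond n = 20 a normal approximation
with tie and continuity corrections takes over (irrelevant at this
cohort scale). The Shapiro–Wilk gate recommends the nonparametric
path whenever any metric's differences reject normality at 0.05 or
are degenerate.

Problem sizes used in the shipped tests and acceptance checks: exact
enumeration cross-checked against brute force up to n = 12, null
calibration with 500 cohorts of 11 pairs at α = 0.1, convergence and
tuning exercised on meshes of a few thousand triangles and ODE runs
of tens of cycles — sizes chosen so the full suite documents the
claimed properties in well under a minute of compute. No
multiple-testing correction is applied across metrics, matching
practice in this literature; at α = 0.1 over ten metrics occasional
spurious flags in null cohorts are expected and are quantified by the
calibration test.

## Known limitations

* The 0D tuner targets the lumped inlet-equivalent node; a 3D solver
  coupled to the tuned RCR values will see slightly different
  systolic/diastolic values at its inlet.
* Synthetic surfaces are idealized (straight tube, hemisphere,
  two-direction oscillation); they validate bookkeeping and
  statistics, not hemodynamic realism.
* `region` labels are taken as given; dome/neck detection and
  impingement clipping are out of scope.
* The exact test's discreteness means attainable significance levels
  at n = 11 sit just below nominal α; the calibration test bounds the
  effect.
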