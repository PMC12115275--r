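---
title: "Methods: the SeDeM expert system as implemented in sedem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SeDeM expert system as implemented in sedem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedem)
```

## The model

The SeDeM expert system scores a powder's suitability for direct
compression from twelve rheological parameters, each standardized onto a
common 0–10 "radius" scale and displayed on a 12-axis radar diagram. The
twelve parameters, their units and acceptable ranges are:

```{r}
sedem_transforms()
```

Five of them are measured directly (cohesion index, angle of repose, flow
time, loss on drying, hygroscopicity); the others derive from two density
measurements and a sieve analysis:

* bulk density $D_a = m / V_0$ and tapped density $D_c = m / V_{1250}$
  (or $m / V_{2500}$ when the volume still settled by more than 2 mL
  between 500 and 1250 taps — the record must then contain the extended
  series, otherwise the computation refuses rather than guess);
* interparticle porosity $I_e = (D_c - D_a)/(D_c D_a)$, Carr index
  $IC = 100\,(D_c - D_a)/D_c$, Hausner ratio $IH = D_c / D_a$;
* angle of repose $\alpha = \arctan(h/\bar r)$ from the cone height and the
  mean of four base radii;
* fines fraction $\%Pf$: the pan percentage below the 0.05 mm sieve;
* relative homogeneity index
  $I_\theta = F_m / \big(100 + \sum_{i \ne m} |d_m - d_i|\,F_i\big)$,
  where $F_m$ is the majority sieve fraction and $d$ are fraction mean
  diameters.

Each standardization rule is affine and sends the favorable end of the
acceptable range to radius 10 (e.g. radius $= 10v$ for the densities,
$v/5$ for the Carr index, $(30 - 10v)/2$ for the Hausner ratio,
$500v$ for the homogeneity index); values mapping outside $[0, 10]$ are
clamped. The twelve radii aggregate twice:

* **incidence factors** — five named groups partitioning the radii
  2/3/3/2/2: Dimensions ($D_a, D_c$), Compressibility ($I_e, IC, Icd$),
  Flowability ($IH, \alpha, t''$), Lubricity/Stability ($\%HR, \%H$),
  Lubricity/Dosage ($\%Pf, I_\theta$); each summarized by its mean radius;
* **global indices** — the parametric profile index $IPP$ (mean of all 12
  radii) and the Good Compression Index $IGC = IPP \times f$, where $f$
  is the ratio of the diagram polygon's area to the circumscribing
  circle's. $IGC > 5$ indicates suitability for direct compression.

## Numerical choices

**Reliability factor.** For a regular 12-gon the exact area ratio is
$(12/2\pi)\sin(\pi/6) = 0.9549$, but the constant used by the expert
system's validated worksheets — and the only value that reproduces the
conventional reported IGC figures — is 0.952. `reliability_factor()`
returns the printed constant by default and the geometric ratio under
`mode = "geometric"`.

**Homogeneity-index diameters.** Fraction mean diameters are midpoints of
the bounding apertures in micrometers (the only unit choice that puts
$I_\theta$ in its documented 0–0.02 range for realistic powders); the pan
uses the midpoint of 0 and the finest aperture (25 µm for the default
stack) and the coarsest fraction is bounded above by a configurable
`top_bound_mm` (default 0.5 mm, matching the 0.6 mm pre-sieving practice
for blends). A tie for the majority fraction is resolved deterministically
to the coarser fraction, with a warning.

**Two aggregation paths for IGC.** `good_compression_index()` averages the
12 radii by default. It can instead take the count-weighted mean of the
five incidence-factor means (`from = "incidences"`), using externally
reported incidences when a profile carries them. The bundled reference
characterization needs this second path for the two L-HPC grades: their
published Lubricity/Stability incidence is internally inconsistent with
their published per-parameter radii, and only the incidence path
reproduces their reported IGCs (4.12, 4.35). The package keeps both
numbers and surfaces the discrepancy instead of silently "fixing" either.

**Rounding.** All internal computation carries full precision. Reported
and compared values are rounded to 2 decimals, half away from zero
(`sedem_round()`), which is the convention all reference values follow
(e.g. a lubricity/dosage incidence of 4.525 reports as 4.53).

**Negative hygroscopicity.** A sample that loses weight at 76% RH would
standardize above radius 10; since the 20–0 range presumes non-negative
uptake, `moisture_params()` floors it to zero with a warning.

**Replicates.** Given several replicate datasets for a material,
parameters are computed per replicate and averaged *before* radius
transformation; per-replicate profiles remain available by profiling each
dataset separately.

## Formulation design

A deficient API (compressibility incidence $R_P$) is corrected with an
excipient of higher compressibility incidence $R_E$; assuming the blend
incidence interpolates linearly in composition, the excipient percentage
for a target radius $R$ is

$$CP = 100 - \frac{R_E - R}{R_E - R_P} \times 100 .$$

`corrective_excipient_pct()` implements this on the binary API/excipient
pair, erroring (not extrapolating) when $R > R_E$ or $R < R_P$; `r_sweep()`
evaluates the decreasing target series 5.0, 4.5, 4.0, 3.5 and flags
infeasible targets. The design consumes incidences at the 2-decimal
reporting precision, which is what reproduces the reference composition
table exactly. The fixed lubricant trio (talc 2.36%, colloidal silicon
dioxide 0.14%, magnesium stearate 1.00%) is layered on afterwards:
API% $= 100 - CP - 3.5$, and the tablet weight carrying a fixed dose is
$\text{dose} / (\text{API\%}/100)$.

One bundled excipient (PARTECK ODT) illustrates a real upstream ambiguity:
its reported compressibility incidence (4.91) makes the 5.0 target
infeasible, yet its reference composition row back-solves exactly to an
incidence of 5.25. The fixture stores both values; the sweep flags the
infeasibility under 4.91 and reproduces the row under 5.25.

## Tablet quality control

`evaluate_cqa()` checks a batch against machine-readable QTPP/CQA limits:
diameter strictly below 7 mm, disintegration within 180 s, friability
$100\,(W_1 - W_2)/W_1$ not more than 1.0% (a value exactly at the limit
passes at-limit with a warning), and a 25–60 N hardness window. The
hardness window is a *flag*, not a hard failure, by default: somewhat
harder tablets are routinely accepted when disintegration and friability
hold, and the reference data include exactly such a batch. Weight
variation follows the compendial rule: per-unit deviation bands of 10%
(mean < 80 mg), 7.5% (80–250 mg) or 5% (> 250 mg), with at most two units
beyond the band and none beyond twice it.

## The synthetic-data generator

`simulate_powder_dataset()` builds raw measurement records whose
recomputed parameters equal a stated ground truth: a 100 g density charge
with volumes back-computed from the target densities (the tap series is
shaped to keep the 500/1250 gap within 2 mL), a cone of 5 cm base radii
and matching height, triplicate flow times, 100 g drying/humidification
weights, ten tablets at the target breaking force, and a sieve
composition solved to hit the target $(I_\theta, \%Pf)$ pair exactly.

The sieve composition is found deterministically: candidate majority
fractions are tried in order; within a candidate, non-majority mass is
spread with distance-decay weights $w_i \propto e^{-\lambda |d_m - d_i|}$
and either the majority mass (closed form) or $\lambda$ (bisection on the
monotone weighted-mean distance) is solved for the exact target. A solver
was preferred over a fixed-step grid search because it is just as
deterministic and removes grid-resolution error from the closure tests.

Noise is multiplicative Gaussian on the raw instrument readings, with
per-instrument relative standard deviations (`volume`, `weight`, `force`,
`time`, `length`, `sieve`), truncated where necessary to preserve record
invariants (volumes non-increasing along the tap series, dry weight not
above wet weight, non-negative forces; sieve fractions renormalized to
100%). Identical seeds give byte-identical datasets.

The generator emulates *measurement* variability around a fixed powder,
not the powder physics: it does not model inter-batch material
variability, correlated errors across instruments, operator effects, or
any dependence of hardness and disintegration on composition. Passing
closure and recovery tests therefore validates the computational chain —
measurements to parameters to radii to indices — not the predictive power
of the SeDeM score for a new material.

`recovery_report()` runs the Monte-Carlo loop: at zero noise every bias
and RMSE is zero, and the IGC recovery error grows with the noise level.
The test suite uses 30–100 replicate datasets per report and 7 reference
profiles for closure, sizes chosen to keep the whole suite comfortably
interactive while leaving the Monte-Carlo conclusions stable across seeds.

## Known limitations

* The blend-radius interpolation behind the dose equation is linear by
  assumption; real blends can deviate, which is why the reference data
  include measured blend profiles (F13/F14) for comparison.
* Tablet diameter is tooling-dependent and is consumed as a measured
  input, never predicted.
* The homogeneity-index solver targets the default four-sieve stack;
  unusual stacks may admit targets outside its search families, in which
  case it errors as infeasible rather than approximating.
* Reported-incidence aggregation trusts the external incidences as given;
  it is the caller's responsibility to prefer the radii path when both
  are consistent.
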