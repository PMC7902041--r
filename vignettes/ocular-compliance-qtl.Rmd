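---
title: "From perfusion traces to QTLs: the models behind ocuqtl"
author: "ocuqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From perfusion traces to QTLs: the models behind ocuqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocuqtl)
```

## The measurement problem

Ocular compliance, phi = dV/dP, is the volume an eye takes up per unit rise
in intraocular pressure (IOP). It is an integrative readout of corneoscleral
stiffness and therefore a natural quantitative trait for mapping genes that
shape ocular biomechanics in recombinant inbred (RI) mouse panels such as
BXD. ocuqtl implements the full chain from raw stepped-pressure perfusion
recordings of enucleated eyes to a genome-wide linkage scan, together with a
synthetic-data generator that lets every stage be verified against known
ground truth.

## The lumped-parameter perfusion model

A perfusion rig holds an applied reservoir pressure $P_a$ behind a needle
and capillary of resistance $R_n$ (mmHg·s/nl). The eye sits at pressure $P$,
drains aqueous humor with outflow facility $C$ (nl/s/mmHg), and may creep
viscoelastically. The state equations are

$$\phi(P)\,\frac{dP}{dt} = \frac{P_a - P}{R_n} - C\,P -
  \frac{dV_{creep}}{dt}, \qquad
  \frac{dV_{creep}}{dt} = \frac{c\,(P - P_0) - V_{creep}}{\tau},$$

with the empirical pressure dependence of compliance

$$\phi(P) = \phi_r\,\frac{P_r + \gamma}{P + \gamma},$$

where $\phi_r$ is the compliance at the reference pressure $P_r = 13$ mmHg
(the normal IOP of C57BL/6J mice) and $\gamma$ (mmHg) controls how steeply
compliance falls with pressure. `sim_perfusion()` integrates these equations
with `deSolve::lsoda` over a stepped applied-pressure protocol and adds
independent Gaussian sensor noise to the recorded pressure and flow.

Units are fixed package-wide: pressure mmHg, flow nl/s, volume nl, time s;
only reporting boundaries convert (volume to µl, modulus to kPa).

### Protocol defaults

The literature on these rigs does not pin down one protocol, so the
generator's defaults are chosen once as a realistic configuration and kept:
baseline 8 mmHg, nine ascending then eight descending 1.5 mmHg steps (so
the plateaus straddle the 13 mmHg reference), 240 s per level (about ten
pressure time constants, letting each plateau settle), 2 Hz sampling.
Sensor noise defaults to 5% of natural scales: 0.075 mmHg on pressure (5%
of a step) and 0.15 nl/s on flow (5% of the peak needle flow). Eye defaults
(phi_r ≈ 45 nl/mmHg, gamma ≈ 10 mmHg, facility 0.05 nl/s/mmHg, needle
resistance 0.5 mmHg·s/nl, mass 21.1 mg at density 1.103 mg/µl) sit at the
center of the murine ranges the analysis targets.

## Two per-step compliance estimators

**Volume Filling (VF).** Over one applied step, the net volume entering the
eye is the integral of measured inflow minus outflow,
$\Delta V = \int (q_{in} - C\,P)\,dt$ (trapezoidal quadrature), and
$\phi = \Delta V / \Delta P$ with $\Delta P$ taken between plateau means
(trailing 25% of each level). This is a *secant* estimate, assigned to the
step midpoint pressure. Both ascending and descending steps are used.
Steps with $|\Delta P| < 0.2$ mmHg are rejected as uninformative.

**Step Response (SR).** The measured pressure transient after an ascending
step is fitted to the model above with creep omitted and $(\phi, \gamma)$
free, $C$ fixed at the per-eye plateau-regression estimate and $R_n$ known
from rig calibration. Because the governing equation is separable, its
solution is available in closed form as $t(P)$:

$$t(P) = \frac{\phi\,(P_0+\gamma)}{\beta\,(P_\infty+\gamma)}
  \ln\!\frac{(P+\gamma)(P_\infty-P_0)}{(P_0+\gamma)(P_\infty-P)},
  \quad \beta = \tfrac{1}{R_n} + C,\; P_\infty = \tfrac{P_a}{R_n \beta}.$$

The fit inverts this with a monotone spline rather than re-integrating the
ODE numerically at every iteration; the generator's independent numerical
integration provides the cross-check in the round-trip tests. The SR
estimate is a *local* compliance anchored at the pre-step plateau pressure.
The Levenberg–Marquardt fit is multi-started over $\gamma$ and $\phi$
initialisations, and a fit whose compliance lands on its box boundary is
treated as a failed step rather than an estimate — under sensor noise a
single-basin fit occasionally collapses, and discarding such steps keeps the
per-eye law fit clean.

**Outflow facility.** One OLS regression of plateau-mean flow on
plateau-mean pressure per eye gives $C$ (slope) with its standard error;
the intercept is kept as a diagnostic and a negative slope is flagged but
retained. The same $C$ is held fixed in both estimators.

## Reference compliance, normalization, and uncertainty

`fit_compliance()` fits $\phi(P)$ above to the per-step estimates by
weighted nonlinear least squares (weights $1/se^2$, unit weights if SEs are
unavailable), multi-started over $\gamma \in \{1, 3, 10, 30, 100\}$ with
$\gamma > 0$ enforced. The reported uncertainty on $\phi_r$ is the standard
error from the weighted fit. Volume is mass divided by the published eye
density 1.103 mg/µl, and $\phi_{norm} = \phi_r / V$ (nl/mmHg/µl) removes
the eye-size dependence of compliance.

## Quality control

Three rules run in a fixed order, separately per method, each recomputed on
the full record set so the cascade is idempotent:

1. eyes whose relative SE on $\phi_r$ strictly exceeds the 85th percentile
   of the cohort are flagged (the "top 15th percentile of uncertainty");
2. of each animal's pair of unflagged eyes, the one with larger SE is
   flagged (ties break OD before OS, deterministically); eyes pair by
   animal identifier, derived from the eye id when absent;
3. within each strain, surviving $\phi_{norm}$ values outside
   $[Q_1 - 1.5\,IQR,\; Q_3 + 1.5\,IQR]$ are flagged.

All percentiles and quartiles use linear interpolation of order statistics
(`stats::quantile` type 7) — the one convention used package-wide. Counts
reconcile at every stage (input = kept + flagged) and each flag names its
rule.

## Strain phenotypes, heritability, modulus

Kept eyes aggregate to per-strain means with SDs and t-based 95% CIs; a
one-way ANOVA across strains is attached as a diagnostic. Heritability uses
the dispersion form $H^2 = V_g/(V_g + V_e)$ with $V_g$ the **standard
deviation** of strain means and $V_e$ the **mean of within-strain standard
deviations** — implemented literally in this SD form, which is the
convention this analysis tradition reports even though the symbols suggest
variances; `heritability(..., form = "variance")` offers the variance-based
variant. Users comparing against variance-component estimators should note
the SD form generally differs from them.

The effective tensile modulus of the corneoscleral shell treats the eye as
an isotropic, incompressible, homogeneous thin-walled sphere:

$$E_{eff} = \frac{3R}{4t}\left(\frac{V}{\phi} + P\right),
  \qquad R = \left(\frac{3V}{4\pi}\right)^{1/3},$$

evaluated at 13 mmHg with central corneal thickness as the thickness
surrogate, and converted via 1 mmHg = 0.133322 kPa. Strains without a
thickness value simply drop out of the modulus analysis.

Method agreement uses Bland–Altman summaries of paired VF−SR values (mean
bias, ±1.96 SD limits, difference-on-mean trend slope). With viscoelastic
creep enabled in the generator the VF estimate exceeds the SR estimate —
VF integrates the creep volume over the whole step while the SR fit is
dominated by the fast elastic transient — and with creep off the two agree
to estimator tolerance. This is the package's mechanistic account of why
the two methods can disagree on real eyes.

## Interval mapping

Genotypes are homozygous B/D mosaics. Between typed markers, the expected
D-allele dosage conditions on the nearest typed flanks under a two-state
Markov chain whose per-interval switching probability is the sib-mating RI
expansion $R = 4r/(1+6r)$ of the Haldane recombination fraction $r$ of the
cM gap. At typed markers the dosage is the call itself; strains untyped on
a whole chromosome get dosage 0.5 there with a warning. The evaluation grid
is the marker set plus 1 cM pseudomarkers, with Mb positions interpolated
piecewise-linearly through the map. (The RI expansion does not compose
exactly across adjacent intervals; conditioning interval-by-interval on the
nearest typed flanks is the standard approximation for near-fully-typed RI
panels, and no multi-marker HMM is attempted.)

Haley–Knott regression of equally weighted strain means on dosage gives,
at each position, $LRS = n \ln(RSS_0/RSS_1)$ (LOD = LRS/2ln10), the slope
as additive effect (positive = D allele increases the trait, with the
half-difference between predicted parental values alongside), and
$1 - RSS_1/RSS_0$ as variance explained. No small-sample correction is
applied to the likelihood form, and no shrinkage of effect sizes — peak
variance-explained values in small panels are overestimates, and reports
should treat them as such.

Significance is empirical: phenotypes are permuted across strains, each
permutation rescanned, and the genome-wide maximum LRS recorded; the
significant and suggestive thresholds are the 0.95 and 0.37 quantiles of
that sample (genome-wide p < 0.05 and p < 0.63), 2000 permutations by
default. Peaks are local maxima above the suggestive threshold, bounded by
the nearest typed markers beyond a 1.5-LOD drop, with the candidate window
extending those bounds by ±1 Mb — the mapping precision RI genotyping
density supports.

## The synthetic cohort and what passing tests mean

`sim_trait()` plants one additive QTL: the allelic effect is scaled so the
QTL explains a requested fraction of strain-mean variance given the
realized dosage variance and the strain-level environmental SD; eye-level
noise adds within-strain spread. Defaults (base 2.35 nl/mmHg/µl, strain and
eye SDs 0.21) put the simulated panel in the regime the real measurements
occupy: with 20 strains × 8 eyes and 5% sensor noise the pipeline returns
$H^2 \approx 0.5$ and recovers strain means to well under 1% RMS
(the acceptance checks assert < 3%, measured against the true values of the
eyes each strain mean actually averages, so the number isolates estimation
error rather than QC sampling attrition).

The generator emulates the statistical and physical structure the analysis
assumes — first-order outflow, one creep mode, Gaussian sensor noise,
density constant across strains, rig compliance calibrated out. Real
perfusions add features it does not model (cannulation leaks, corneal
hydration drift, post-mortem changes, non-Gaussian artifacts), so passing
tests certify the estimators and the mapping machinery, not robustness to
every experimental pathology.

A note on mapping power: at the default architecture (QTL explaining ~37%
of strain-mean variance in a 20-strain panel) the expected LRS at the QTL,
$-20\ln(1-0.37) \approx 9$, sits *at* the typical suggestive threshold
(~10–11 for a 19-chromosome, ~1400 cM genome), so the probability of a
suggestive-or-better peak within 10 cM of the truth is only ~0.5 — the
acceptance script reports the measured value. This is a property of the
design, not of the implementation: the same machinery maps a QTL explaining
60% of variance, or the same QTL in a 40-strain panel, in ~97% of
replicates. It matches the observation that real peaks in this effect-size
regime reach only suggestive significance.

## Numerical choices and degenerate inputs

* ODE integration: `lsoda` with rtol 1e-10; any non-finite state aborts and
  names the offending applied level.
* SR inversion grid: 400 points in $u = \ln\frac{P_\infty-P_0}{P_\infty-P}$
  up to $u = 30$, monotone Hyman spline; inversion error is ~1e-6 mmHg,
  far below sensor noise.
* The Eq.-1 and SR fits reject rather than extrapolate: fewer than 3
  distinct pressures, non-convergent multi-starts, or box-pinned
  compliances are errors/rejections, with $\gamma$ pinned at its bounds
  flagged.
* Degenerate traces (a single applied level, or a ramp with no plateau) are
  rejected at segmentation; plateau statistics need at least 4 samples.
* All randomness flows from one master seed, split deterministically per
  stage; identical seeds give byte-identical outputs.

## Problem sizes used in the shipped checks

Unit tests run on short protocols (60–240 s steps) and small panels; the
end-to-end checks use the full 20 × 8 cohort at the default protocol, 500
permutations per scan, 100 replicate panels for mapping power, and 500
replicate null scans for threshold calibration. These sizes give
Monte-Carlo bands comfortably tighter than the tolerances they check.

## A worked example

```{r example, eval = FALSE}
library(ocuqtl)
res <- run_pipeline(run_config(seed = 1, n_perm = 500))
print(res)
plot(res$per_method$VF$scan, thresholds = res$per_method$VF$thresholds)
```

## Known limitations

* Heritability is the literal SD-based panel statistic, not a mixed-model
  estimate; no covariates (sex, age) are modelled.
* The trait architecture is purely additive; no epistasis, dominance, or
  X-chromosome handling.
* Facility is assumed pressure-independent within a perfusion, and rig
  (non-ocular) compliance is assumed calibrated out.
* Effect sizes at peaks are not corrected for RI resampling inflation.
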