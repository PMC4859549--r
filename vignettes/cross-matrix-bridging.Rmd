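---
title: "Methods: simulating and bridging praziquantel enantiomer PK across sampling matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and bridging praziquantel enantiomer PK across sampling matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pzqbridge)
library(dplyr)
```

This vignette documents the statistical and numerical methods in
`pzqbridge`: the synthetic cohort model and its calibration, the
non-compartmental analysis (NCA) conventions, the agreement statistics,
the bioanalytical QC procedures, and the known limitations of the
generator. It is the methods reference for the package; the README shows
the corresponding worked example.

## 1. The pharmacokinetic model

Each analyte — the praziquantel enantiomers R-PZQ and S-PZQ and the
metabolite *R*-trans-4-OH-PZQ — follows a one-compartment model with
first-order absorption. For a per-kilogram dose $D$ given at time
$\tau$, the plasma concentration contribution is

$$
C(t) = s \cdot \frac{D}{V}\,
       \frac{k_a}{k_a - k_e}
       \left(e^{-k_e (t-\tau)} - e^{-k_a (t-\tau)}\right),
\qquad t \ge \tau,
$$

and the default triple-dose regimen (25 mg/kg at 0, 4 and 8 h) is
handled by superposition over the doses actually taken. Dosing is per
kilogram and the apparent volume is expressed per kilogram, so body
weight cancels from concentrations; weight is still simulated (log-normal,
median 56 kg) because it is part of a realistic cohort record. The
dimensionless exposure scale $s$ absorbs bioavailability and clearance
differences between analytes, including the fact that the "metabolite
dose" is really parent drug converted on first pass — the metabolite is
modelled as its own lumped input rather than through an explicit
parent–metabolite link (see §7).

Per-analyte elimination rates are set from the target terminal
half-lives via $k_e = \ln 2 / t_{1/2}$ with $t_{1/2}$ = 1.1, 3.3 and
6.4 h for R-PZQ, S-PZQ and the metabolite, and a common absorption rate
$k_a = 1.5\,\mathrm{h}^{-1}$, which places the post-third-dose peak at
roughly 9–10 h, consistent with the sampling design below.

### Matrices

Venous blood and DBS concentrations are plasma times a per-analyte
blood:plasma partition coefficient $r$ (0.80 for both parent
enantiomers, 1.15 for the metabolite). DBS measurements carry extra
assay noise (§3) but no separate bias term: the DBS assay is assumed
volumetrically controlled and IS-normalised, so its systematic
difference from plasma is the same partitioning phenomenon as venous
blood.

### Sampling schedules

Venous samples (plasma and whole blood) use an 11-point grid: 0, 2, 4,
6, 8, 8.5, 9, 10, 11, 12, 24 h. DBS uses two interleaved six-point
schedules, A (0, 4, 8, 9, 11, 24 h) and B (0, 2, 6, 8.5, 10, 12 h),
assigned by position in the cohort (subjects 1–5 → A, 6–9 → B, cycling).
For the default nine-subject cohort this yields 99 venous plasma, 99
venous blood and 54 DBS records per analyte.

## 2. Calibration of the exposure scales

The target plasma medians for AUC(0–24) are 1.1, 9.0 and 188.7
µg/ml·h for R-PZQ, S-PZQ and the metabolite. A subtle point drives the
calibration design: those targets are *measured* quantities — trapezoid
estimates on the sparse venous grid with LLOQ censoring — not the true
integral of the continuous model. The two differ materially for the
extreme analytes: the trapezoid misses the sharp absorption peaks of
fast-eliminating R-PZQ (and its profile is BLQ-truncated before 24 h),
while it overestimates the convex decay of the slowly eliminated
metabolite. Calibrating $s$ so that the closed-form
$\mathrm{AUC}_\infty$ matches the target would therefore mis-centre the
medians that the package's own NCA reports.

Instead, `default_analyte_models()` starts from the closed-form value
and then applies a two-step fixed-point correction: it evaluates the
noiseless model on the venous grid, censors at the LLOQ, runs the
package's own trapezoid (with terminal extrapolation where applicable),
and rescales $s$ by target/measured. Two iterations suffice because the
measurement operator is homogeneous in $s$ except for the (weak) LLOQ
truncation; after them the noiseless measured AUCs equal the targets to
numerical precision.

### Between-subject variability

Subject-level variability multiplies $k_e$ and $V/F$ by independent
median-preserving log-normal factors, $\exp(\sigma Z)$ with
$Z \sim N(0,1)$, so that cohort medians stay centred on the calibrated
values. The coefficients (12 % for each enantiomer, 8 % for the
metabolite) were chosen, before any seed-level checking, to reproduce
the dispersion of the non-outlier subjects in the target ranges: the
metabolite's reported inter-quartile spread is proportionally tighter
than the parents'. In addition, one subject per nine (configurable
`outlier_fraction`) receives a uniform 2–10-fold boost to the exposure
scale of all analytes, reproducing the occasional extreme-exposure
participant seen in field cohorts; because the boost is a scale factor
on $s$, it moves AUC and Cmax together and leaves $t_{1/2}$ untouched.

## 3. Noise, censoring and derived datasets

Measured concentrations are the model value times a multiplicative
normal error with CV 8 % (plasma, blood) and an additional 6 % for DBS,
truncated at zero. Values below the analyte LLOQ (0.01 µg/ml for the
enantiomers, 0.1 for the metabolite) are reported as BLQ (`conc = NA`,
`blq = 1`); `censor_to_range()` additionally flags values above the
ULOQ (2.5 / 2.5 / 25 µg/ml) as `above_uloq` but retains them, since
dilution-and-reassay is not modelled. Censoring is idempotent by
construction and tested as such.

All randomness is driven by deterministic per-subject substreams:
`subject_seed(base, i, stream)` combines the base seed, subject index
and stream index through fixed large primes modulo $2^{31}-1$, so
adding subjects to a cohort never perturbs existing subjects'
profiles, and every downstream dataset (ISR replicates, partition
experiments, egg counts) draws from its own stream.

`generate_isr_pairs()` re-assays a fixed fraction (default 56 %) of
quantifiable records with an independent repeat CV of 10 %, chosen so
the expected within-±20 % rate sits in the high-90s typical of a
passing incurred-sample-reanalysis (ISR) exercise.
`generate_partition_experiment()` simulates triplicate spiked
blood/plasma pairs at two concentration levels per analyte with a
shared per-replicate instrument factor that cancels under internal-standard
(IS) normalisation, so `partition_ratio()` recovers $r$ exactly in the
noiseless limit. `generate_egg_counts()` draws quadruplicate Kato-Katz
smears from a negative-binomial model (pre-treatment geometric-mean
scale ≈ 3 650 eggs per gram, dispersion 2), with post-treatment counts
zeroed for cured subjects.

## 4. Non-compartmental analysis conventions

* **AUC** — linear trapezoid on the piecewise-linear interpolant from
  the first observation to $\min(t_\text{last}, 24)$. BLQ handling is
  positional: leading BLQ values are set to 0, embedded BLQ values are
  bridged over, trailing BLQ values truncate the profile.
* **Terminal slope** — ordinary least squares of $\log C$ on $t$ over
  candidate windows of the last $m \ge 3$ quantifiable points strictly
  after Tmax, choosing the window with maximal adjusted $R^2$ among
  fits with $\lambda_z > 0$. On the six-point DBS schedules the
  post-peak segment can contain only two points (the noiseless Tmax
  falls at 8.5–10 h on schedule B); `nca_analyze()` then falls back to
  the exact two-point slope, flagged `lambda_z_sparse`. A two-point
  terminal estimate is a pragmatic, conventional compromise on sparse
  capillary designs; its price is visible in the wider spread of
  DBS-derived half-lives relative to venous ones.
* **Extrapolation** — profiles ending before 24 h are extended by
  $(C_\text{last}/\lambda_z)\,(1 - e^{-\lambda_z (24 - t_\text{last})})$
  when $\lambda_z$ is available (flag `extrapolated`, with the
  extrapolated fraction reported); otherwise the AUC is truncated at
  $t_\text{last}$ and flagged `truncated;lambda_z_missing`.
* **Cmax/Tmax** — maximum observed concentration, earliest time on
  ties. Medians use the mean-of-central-order-statistics convention
  for even $n$.

The trapezoid is verified against a $10^5$-point fine-grid integration
of the interpolant, and the terminal slope against exact exponentials,
both to tight tolerances, in the test suite.

## 5. Agreement statistics

Cross-matrix agreement is computed on percentage ratios
$100 \cdot C_\text{test} / C_\text{ref}$ of time-matched quantifiable
pairs (plasma as reference). Because each subject contributes many
ratios, the conventional Bland–Altman limits of agreement (mean ±
1.96 SD over all ratios) understate the uncertainty; the
repeated-measures variant partitions variance by one-way ANOVA:

$$
\hat\sigma^2_\text{between} =
  \max\!\left(0, \frac{MS_B - MS_W}{n_0}\right),
\qquad
n_0 = \frac{N - \sum_i n_i^2 / N}{k - 1},
$$

with total SD $\sqrt{\hat\sigma^2_\text{between} + MS_W}$ and limits
of agreement at the grand mean ± 1.96 × total SD. Confidence intervals
use the $t$ distribution with subjects (not observations) as the
effective sample size and
$SE(\mathrm{LoA}) = s\sqrt{1/m + 1.96^2 / (2(m-1))}$. With a single
observation per subject the estimator degrades gracefully to the
conventional form (`singleton_fallback` flag). The implementation is
verified against `stats::aov` mean squares on unbalanced designs to
$10^{-12}$.

`parameter_ratio_table()` applies the same ratio machinery to NCA
parameters (AUC, $t_{1/2}$, Cmax, Tmax), where each subject contributes
one ratio and the conventional limits are appropriate.

## 6. QC and efficacy definitions

ISR uses the standard acceptance rule: percentage difference
$100\,(C_\text{repeat} - C_\text{original}) / \bar{C}$, pass if at
least two-thirds of pairs fall within ±20 % (boundary inclusive). The
statistic is antisymmetric in its arguments and bounded by ±200 %,
properties the tests check directly. Kato-Katz eggs per gram are
$6 \times$ the sum of the four smear counts (each smear represents
1/24 g of stool); geometric means use a shifted $\log(x+1)$ form when
zeros are present, flagged in the output; cure rate is the percentage
of assessed subjects with zero post-treatment EPG, and the
egg-reduction rate is $100\,(1 - \mathrm{GM}_\text{post} /
\mathrm{GM}_\text{pre})$.

## 7. Realism, problem sizes and limitations

The generator is calibrated to reproduce cohort-median plasma exposure,
half-life hierarchy, cross-matrix partition ratios and censoring
patterns for a nine-subject, three-analyte, three-matrix design — the
problem size used throughout the tests, along with 20-seed replication
for the distributional checks. Within that scope it is deliberately
simple, and the following limitations matter for interpretation:

* **Nominal times only.** Samples are taken exactly on the scheduled
  grid; no deviations or missing samples beyond LLOQ censoring.
* **Lumped metabolite kinetics.** The metabolite has its own absorption
  input rather than being formed from parent concentrations, so
  parent–metabolite correlations within subject arise only through the
  shared outlier mechanism, not through shared clearance.
* **No hematocrit correction.** Hematocrit is simulated as a cohort
  covariate but does not feed the blood:plasma ratio; $r$ is a fixed
  per-analyte constant, so the generator cannot produce
  hematocrit-driven DBS bias.
* **Stationary assay error.** Noise CVs are concentration-independent;
  real assays are noisier near the LLOQ.
* **No enterohepatic or nonlinear effects.** First-order kinetics
  throughout; dose-nonlinearity in clearance is not modelled.

These choices keep every component analytically checkable — each
numerical routine in the package is tested against an independent
oracle or a closed form — at the cost of some biological fidelity. The
configuration object (`simulation_config()`) exposes all rates, scales,
noise levels and censoring limits, so alternative calibrations can be
explored without code changes.
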