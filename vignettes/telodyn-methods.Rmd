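---
title: "Methods: densitometric TRF quantification and blood-and-muscle telomere dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: densitometric TRF quantification and blood-and-muscle telomere dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodyn)
```

## The blood-and-muscle model

Telomeres shorten with each somatic cell division. Leukocyte telomere
length (LTL) measured in adults therefore mixes two quantities: telomere
length at conception/birth, and the cumulative replicative attrition of
the haematopoietic compartment since then. Skeletal muscle is minimally
proliferative, so muscle telomere length (MTL) measured in the same
individual is a proxy for telomere length early in life, and the LTL/MTL
ratio isolates cumulative leukocyte attrition — most of which accrues
during the highly replicative first years of life. `telodyn` implements
the three computational layers this design needs:

1. **trfquant** — mean terminal restriction fragment (TRF) length from
   Southern-blot lane densitometry;
2. **dynamics** — descriptive statistics of LTL, MTL and their ratio
   (age slopes, age/sex-adjusted means, pairwise tests);
3. **assoc** — SNP quality control and gated additive association
   analysis of the three phenotypes, plus a pairwise epistasis scan;

together with a **synthetic-data** layer that simulates both the raw
measurement objects (gel lanes, ladders, duplicate membranes) and
genotyped cohorts with known ground truth, so that every downstream
stage has an oracle.

## Mean TRF from lane densitometry

A digested DNA sample resolved on an agarose gel and hybridised with a
telomeric probe produces a smear of optical density (OD) along the lane.
The probe signal at a given position is proportional to the *mass* of
telomeric DNA there, i.e. to (number of molecules) × (fragment length).
The estimator

$$\widehat{\mathrm{TRF}} \;=\; \frac{\sum_i \mathrm{OD}_i}{\sum_i \mathrm{OD}_i / \mathrm{MW}_i}$$

divides each OD sample by its molecular weight, converting mass back to
molecule counts; the ratio is therefore the molecule-number-weighted
mean fragment length over the window. `mean_trf()` evaluates the sums
over profile pixels whose molecular weight falls in a closed window
(default 3–20 kb), without interpolation onto a kb grid; positions that
map exactly onto a window edge are included (a relative tolerance of
1e-9 absorbs floating-point conversion error). An empty window is an
error, never a silent zero. The estimate is invariant to uniform OD
rescaling, so the absolute scale of the densitometry is irrelevant.

Molecular weights come from a power-law ladder calibration
$\mathrm{MW} = A\,d^{B}$ ($B<0$), fitted by least squares on the log-log
scale by `fit_ladder_calibration()`; noiseless power-law bands are
recovered exactly. Several ladders are resolved across a membrane and
`select_nearest_ladder()` assigns each sample lane the closest one,
breaking ties toward the leftmost ladder (a documented, deterministic
choice).

### Background handling

The paper trail of gel densitometry software rarely documents its
background step, so `subtract_background()` exposes three explicit
methods, always recorded in the profile metadata:

* `rolling_min` (default) — subtract a running minimum over a window of
  10% of the lane; robust to slowly drifting baselines.
* `lane_flanks` — subtract the mean OD of the outer 5% of the lane at
  each end; exact when the flanks are signal-free.
* `none` — identity.

A known limitation, verified on simulated lanes: a running minimum
whose window is narrower than a broad low-amplitude smear subtracts
part of the smear itself and can bias the mean TRF by several percent.
The round-trip validation therefore uses `lane_flanks`, which is
unbiased under the simulator's geometry (the default reciprocal
migration law places the whole 2–25 kb range at 40–500 px of the
10–600 px lane, leaving both flanks clean). On real membranes with
unknown flank behaviour, `rolling_min` remains the safer default; the
choice is a user-visible parameter, not a hidden constant.

### Duplicates and reliability

Each sample is measured in duplicate on separate membranes;
`average_duplicates()` takes the arithmetic mean and raises a QC flag
(not an error) when the pair disagrees by more than 0.5 kb
(configurable). Measurement reliability is summarised by the one-way
random-effects single-measure intraclass correlation ICC(1,1),
$\mathrm{ICC} = (\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+(k-1)\mathrm{MSW})$,
with a 95% CI from the F distribution (Shrout–Fleiss). One-way random is
the appropriate form for replicate membranes, which have no fixed rater
structure. The reliability of the *mean* of $k$ duplicates follows by
Spearman–Brown step-up, $k\,\mathrm{ICC}/(1+(k-1)\mathrm{ICC})$; an ICC
of 0.99 with $k=2$ gives 0.995. `icc()` reports unrounded values
throughout, since step-ups computed from rounded single-measure ICCs
(e.g. 0.98 → 0.9899) need not match step-ups of the unrounded estimate.

## The gel simulator

`simulate_lane_profile()` encodes exactly the assumption the estimator
inverts: each fragment-size atom contributes OD mass proportional to
(molecules × kb), deposited at $d = (m/A)^{1/B}$ with linear splitting
between adjacent pixels, convolved with a Gaussian point-spread
(default SD 2 px), scaled to a fixed total OD mass, then overlaid with
constant background (0.02 OD) and white pixel noise (SD 0.001 OD).
Fixing the *integrated* signal mass rather than the peak height keeps
the signal-to-background ratio of a lane independent of smear width;
mean TRF is scale-invariant, so this normalisation is free. Mass
migrating outside the representable pixel range is an error naming the
offending kb range.

Within-sample TRF smears are modelled by `trf_mixture()` as a lognormal
(right-skewed, the natural choice for a fragment-size distribution)
truncated to 2–25 kb and discretised into 512 atoms; a normal family is
available, and any `data.frame(kb, molecules)` is accepted. The
realised molecule-number mean of the discretised atoms is stored in the
profile metadata as the round-trip truth.

`simulate_membrane()` reproduces the measurement design: leukocyte and
muscle DNA of one individual on adjacent lanes of the same membrane,
ladders at the first, middle and last lane positions, one reference
lane of known TRF length (reported as a between-membrane drift
statistic, with no normalisation applied), and the whole layout
duplicated on a second, independently noised membrane. Pixel noise
alone would make duplicates agree almost perfectly (ICC ≈ 1); the
dominant real source of replicate disagreement is gel distortion, which
the simulator represents as a per-lane multiplicative drift of the
migration scale (lognormal, SD 0.8%). That value puts the duplicate ICC
of quantified lanes in the ≈ 0.99 regime reported for this measurement
technique, which is the regime the reliability machinery is meant to
exercise.

## The cohort generator

`simulate_cohort()` draws, per individual:

* **age** — truncated normal, mean 60, SD 15 years, range 20–94;
* **sex** — Bernoulli, 32% female;
* **genotypes** — independent Hardy–Weinberg draws at each panel SNP's
  MAF; an inbreeding coefficient `hwe_fis` > 0 induces a heterozygote
  deficit for simulating QC failures;
* **MTL** (kb) — mean 8.57 at the reference age, age slope −15 bp/year,
  female−male offset +0.25 kb, residual SD 0.678 kb;
* **gap = MTL − LTL** (kb) — mean 1.86 at the reference age, widening
  by 16 bp/year (so the LTL slope is −31 bp/year), sex offset
  +0.03 kb, residual SD 0.204 kb, plus the per-allele genetic effects;
* **LTL = MTL − gap**.

Three calibration details matter:

1. **Anchoring.** Intercepts are anchored at the analytic mean of the
   truncated age distribution (≈ 59.7 years for the defaults), and sex
   offsets are applied centred on the female fraction, so the
   population means equal the configured means exactly rather than
   approximately.
2. **Residual SDs.** The configured `mtl_sd` (0.678) and `ltl_gap_sd`
   (0.204) are *residual* SDs, derived analytically so that the
   marginal SDs — residual variance plus the age-slope component
   (slope² × truncated-age variance) plus the sex-offset component
   (offset² × f(1−f)) — reproduce 0.72 kb for MTL and 0.84 kb for LTL.
3. **Allele effects.** Panel effects are specified per minor allele on
   log-LTL (natural log). The generator converts each to a kb-scale
   gap increment by solving $\beta = -\delta\,E[1/\mathrm{LTL}]$, with
   $E[1/\mathrm{LTL}]$ evaluated by the second-order moment expansion
   $(1/\mu)(1+\sigma^2/\mu^2)$ from the configuration's implied LTL
   mean and variance. Dosages enter centred ($g - 2\,\mathrm{MAF}$), so
   allele effects perturb neither the population mean nor the variance
   calibration appreciably. Placing genetic effects on the early-life
   gap rather than on MTL is the generative default (effects on the
   attrition component, none on telomere length at birth); `beta_mtl`
   is exposed for counterfactual simulations that put effects on MTL
   instead.

With these defaults the LTL/MTL ratio has mean ≈ 0.78 and an age slope
of ≈ −0.0022 per year *emergently* — the generator is parameterised
only by the separate LTL and MTL means, SDs and slopes, so recovering
the ratio statistics is an internal-consistency check, not a fitted
target. LTL < MTL holds for essentially all individuals (the gap's
total SD is ≈ 0.3 kb against a mean of 1.86 kb, putting the crossing
probability below 1e-9).

What the generator does **not** emulate: linkage disequilibrium between
panel SNPs (draws are independent), population stratification,
genotyping error, non-linear age trajectories, and any LTL–ASCVD
outcome model. Passing tests on this generator therefore demonstrate
correctness of the estimators under the stated model, not robustness to
those real-data complications.

## Association analysis

`compute_maf()` orients every SNP to its minor allele (recording
flips); `hwe_chisq()` compares observed genotype counts with the
$p^2, 2pq, q^2$ expectation (1 df, default exclusion threshold
α = 0.05 — the conventional screening level, since the analysis gate
itself is what controls downstream error); `filter_hwe()` drops
violating SNPs and names each in an exclusion log.

`gated_testing()` implements the hierarchical strategy that limits
multiple testing in small cohorts: stage 1 regresses log-LTL (natural
log; the base is configurable and recorded) on minor-allele dosage with
age and sex as covariates for every QC-passing SNP; only SNPs with
stage-1 p below the gate (default 0.05, nominal and unadjusted —
configurable) are tested in stage 2 against MTL (age + sex) and the
LTL/MTL ratio (age only, since the ratio is not sex-dependent).
Untested cells are reported explicitly as `tested = FALSE`, never as
failed fits. Missing genotypes are handled complete-case per SNP with
the fitted n reported; no imputation is attempted.

`epistasis_scan()` fits, for each SNP pair, the main-effects-plus-
product-term linear model and reports the interaction coefficient with
raw and Bonferroni-adjusted (over tested pairs) p-values. This is a
deliberately plain pairwise-interaction model; combined-phenotype
epistasis machinery is out of scope. Monomorphic SNPs cause the pair to
be skipped with a log entry rather than a failure.

## Numerical and design choices

* **Windows** are closed intervals; the default analysis window is
  3–20 kb.
* **Mann–Whitney** uses midranks with the normal approximation (no
  continuity correction) except when both samples have n ≤ 20 and no
  ties, where the exact distribution is used. **χ²** tests apply no
  Yates correction by default (the convention of genetics tooling);
  both corrections are switchable.
* **Ratios above 1** (LTL > MTL) are flagged, not dropped: they are
  biologically anomalous but can arise in noisy measurements, and
  silent row deletion would bias reliability statistics.
* **Determinism.** Every simulator takes a seed; `run_all()` derives
  per-stage streams from one master seed and records them in the run
  log, so identical configurations give byte-identical outputs.
* **Degenerate inputs** error early with named messages: empty ladders,
  non-monotone band tables, zero OD mass in a window, zero total
  variance in an ICC table, monomorphic dosages, collinear designs.

## Validation problem sizes

The test suite validates the stack at sizes chosen to make Monte Carlo
error small relative to the assertion tolerances while keeping a full
run around a minute: 50 random smear distributions for the gel
round-trip (each within 1% of its known molecule-number mean); 100
replicate cohorts of n = 402 for the dynamics calibration (mean LTL,
ratio, both age slopes); 500 replicate cohorts for recovery of the
largest panel log-LTL effect; and 1000 null-cohort replicates for the
type-I-error calibration of stage-1 testing, checked per SNP against
Bonferroni-adjusted binomial bounds and pooled across SNPs. The
`scripts/acceptance.R` entry point recomputes the headline quantities
from scratch at the same sizes under a caller-supplied seed.

## Limitations

* The interface begins at extracted OD-versus-distance profiles; raster
  gel images, band calling and chemiluminescence physics are out of
  scope.
* The lognormal smear family is a modelling choice; nothing in the
  quantification depends on it, but round-trip accuracy statements are
  statements about that family.
* The reference lane is tracked as a drift statistic only; no
  between-membrane normalisation is applied.
* Association machinery targets a small candidate panel: no
  genome-wide data structures, relatedness correction, or imputation.
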