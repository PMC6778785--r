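---
title: "Pooled selection-and-sequencing phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled selection-and-sequencing phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolselect)
```

## The measurement problem

Phenotyping dozens of isogenic strains for a quantitative, fitness-proximal
trait such as starvation resistance is slow when each strain must be assayed
individually. The alternative implemented here is competitive: pool the
strains into one starving culture of L1-arrested larvae, sample survivors
over a time course, let them recover on food, and sequence the recovered
populations. Strains that survive starvation, recover quickly and reproduce
well increase in relative frequency; sensitive strains decline. A single
sequencing library per time point therefore phenotypes the whole panel at
once, with every strain experiencing an identical environment.

The quantity to be measured is the frequency trajectory $f_s(d)$ of each
strain $s$ over days of starvation $d$, and from it a scalar trait value.

## Strain-unique SNVs as frequency markers

In a pool of homozygous strains, a biallelic SNV at which exactly one
strain carries the alternative allele is a *unique SNV* of that strain: in
pooled reads, the alternative-allele fraction at that site estimates the
strain's frequency directly. `identify_unique_snvs()` extracts these
markers from a genotype panel. Two policies handle missing calls: under
`"strict"` (the default) a variant with any missing call is never unique,
because an uncalled strain might carry the alternative allele; under
`"lenient"` missing calls count as reference. Heterozygous calls in a
supposedly isogenic panel are treated as missing, with a warning.

`infer_frequencies()` estimates
$$\hat f_s = \frac{1}{n_s}\sum_{i \in \mathrm{SNVs}(s)}
  \frac{\mathrm{alt}_i}{\mathrm{ref}_i + \mathrm{alt}_i},$$
the unweighted mean of per-SNV alternative-read fractions. The unweighted
mean (rather than a coverage-weighted one) matches the error analysis
below, which treats each SNV as one independent estimate; a
coverage-weighted option exists (`weight_by_coverage = TRUE`) but is off by
default. SNVs with total coverage below `min_total_reads` (default 1) are
excluded rather than contributing an undefined $0/0$ or a spurious zero. A
strain with no usable SNV in a library is *missing* in that library, never
zero. Estimates from fewer than 16 SNVs are flagged `low_confidence` (see
the error model for where 16 comes from). Frequencies are deliberately not
renormalised to sum to one: each strain's trajectory is used on its own
scale.

## From trajectories to trait values

For each biological replicate, `compute_trait_values()` fits an ordinary
least-squares regression of $\hat f_s$ on day of starvation and keeps the
slope; the **trait value** is the unweighted mean of the per-replicate
slopes. Positive values mean the strain gained representation over the
time course (relatively starvation-resistant), negative values the
opposite. The defaults mirror the experimental design the package
emulates: replicate 1 sampled on days 16 and 21 only (its slope is exactly
a finite difference), replicate 2 on days 1, 7, 14, 21 and 24. The two
replicates are averaged without weighting by their number of time points.
Trajectories need not be linear; the slope is used as a simple, monotone
summary of direction and magnitude of change, which is what a
genome-wide association needs. Libraries where a strain has no usable
marker are dropped from that strain's regression rather than imputed, and
a replicate contributes a slope only if it retains two distinct days.

Because the trait is a slope in *absolute* frequency units, founder
frequency acts as a gain factor: a rare strain's trajectory is compressed
relative to a common strain with the same relative dynamics. The
rank-recovery property test therefore uses equal founder proportions to
isolate the selection signal; under dispersed founders (Dirichlet
concentration 3) the measured Spearman correlation between mortality rank
and trait rank attenuates from about $-0.85$ to about $-0.78$ in our
simulations. This attenuation is a property of the trait definition, not
of the estimator.

## The Poisson error model

How precise is $\hat f_s$? `simulate_proportional_error()` answers by
simulation, mirroring how the data behave: at true frequency $f$ and mean
total per-SNV coverage $\lambda$, the alternative-read count at one SNV is
$\mathrm{Poisson}(\lambda f)$; one simulation draws $n$ such counts (one
per unique SNV), estimates $\hat f$ as the mean of $\mathrm{count}/\lambda$,
and the **mean proportional error** is
$\mathbb{E}\,|\hat f - f| / f$, averaged over 4000 simulations by default.
In the normal regime ($\lambda f n$ large) this approaches the closed form
$$\sqrt{\frac{2}{\pi\, n\, \lambda\, f}},$$
the mean absolute deviation of the limiting normal; the test suite checks
the simulation against this form to within 10% wherever
$\lambda f n \ge 50$. The simulation, not the closed form, is the
definitive number.

At the coverage the package treats as canonical ($\lambda = 1691$), a
strain present at $f = 0.01$ needs 16 unique SNVs to be measured with less
than 5% proportional error — that is the origin of the 16-marker
`low_confidence` threshold — while a strain with only 2 unique SNVs stays
above 5% error until its frequency approaches the 0.10–0.15 range.
Whether the per-SNV total coverage should itself be random is ambiguous in
this kind of design, so both behaviours are implemented: the default holds
the total fixed at $\lambda$; `coverage = "random"` draws it as
$\mathrm{Poisson}(\lambda)$ with the alternative count binomial given the
total. At deep coverage the two agree closely. `error_grid()` evaluates
the full cross-product of coverages, marker counts and frequencies with
per-cell seeds derived from one base seed, and `minimum_requirements()`
inverts it to give the smallest marker count meeting a target error.

## Validation assays

### Logistic survival curves

Manual assays score the fraction of plated worms alive on each day. The
per-replicate model is the three-parameter logistic
$$S(d) = \frac{U}{1 + e^{k (d - t_{50})}},$$
fit by weighted nonlinear least squares (`minpack.lm::nlsLM`, weights
equal to the number plated, so days with more worms scored count more).
**Median survival time** is reported as the fitted $t_{50}$, the day at
half the upper asymptote $U$ — when $U < 1$ this is *not* the day of
absolute 50% survival, which is why the parameterisation is stated
prominently. $U$ is estimated freely in $(0, 1]$ by default; if that fit
fails or is non-identifiable, $U$ is fixed to the earliest-day survival
proportion and the fit retried (`fix_upper = TRUE` forces this). Starting
values are $U_0 = \max p$, $k_0 = 0.5$ per day, and $t_{50,0}$ the first
day at which survival drops below $U_0/2$. Constant survival (e.g.
everything alive) returns a flagged, non-converged fit rather than an
error; fits with no observation below half the maximum warn that $t_{50}$
is an extrapolation.

### Comparing strains

`compare_median_survival()` takes the per-replicate $t_{50}$ values,
tests variance homogeneity across strains with Bartlett's test, and — the
appropriate follow-up when variances are homogeneous — computes pairwise
t statistics using the variance pooled across *all* strains with
$\sum_i (n_i - 1)$ degrees of freedom, which buys power at the small
replicate counts (3–5) typical of these assays. If Bartlett's test
rejects at $\alpha = 0.05$ the function warns that the pooled comparisons
rest on a violated assumption. The type-I error of this procedure is
checked by simulation in the test suite (2000 null datasets).

### Recovery assays and the trait correlation

Brood-size and body-length measurements after extended (eight-day)
starvation are normalised by the same strain's mean after one day of
starvation (`normalize_recovery()`), isolating the starvation effect from
baseline strain differences; one-day values are normalised too, making
their per-strain mean exactly 1. `correlate_trait_with_survival()`
regresses per-strain mean $t_{50}$ on the sequencing trait value and
reports the line and $R^2$ — the package's validation that the pooled
measurement orders strains the way individual assays do.

### The association stage is deliberately naive

`marker_scan()` regresses trait values on 0/1 allele counts one marker at
a time and draws a Bonferroni line at $-\log_{10}(0.05/M)$. It performs
**no population-structure correction** — no kinship matrix, no mixed
model — and every result object says so. In a panel of wild isolates with
strong linkage disequilibrium and relatedness, a naive scan inflates
associations; it is provided as a transparent, dependency-free
reference stage, not as a substitute for a mixed-model GWAS run against a
curated marker set.

## The synthetic-data generator

`sim_config()` fixes the study conditions the rest of the package is
tested under. The generator emulates:

* **Pool composition.** 96 homozygous strains; per-strain unique-SNV
  counts drawn log-normal with median 33 and $\sigma_{\log} = 0.83$
  (chosen so the quartiles fall near 22 and 67, the spread observed in
  real reduced-representation panels), clamped to at least 1 marker.
* **Founder frequencies.** Symmetric Dirichlet with concentration 3:
  day-1 median near $1/96 \approx 0.0104$ with substantial spread. The
  true founder dispersion of such pools is not identifiable from summary
  data; the concentration is an explicit free parameter, chosen once.
* **Selection.** Deterministic infinite-population dynamics
  $$f_s(d) = \frac{w_s f_s(0) e^{-m_s d}}{\sum_k w_k f_k(0) e^{-m_k d}},$$
  with per-day mortality $m_s$ and a recovery weight $w_s$ that folds
  survival, recovery speed and early fecundity into one multiplicative
  fitness term — the same integration the sampling scheme performs.
  Demographic noise is omitted by default because the emulated cultures
  hold millions of larvae; `demographic_n` enables a finite-size
  multinomial resample for sensitivity checks. Default mortality rates
  are gamma with mean 0.1/day and CV 0.71, enough heterogeneity that the
  frequency distribution visibly spreads and its median falls over a
  24-day course. Real pools show an even stronger median decline,
  driven by survival and recovery selection combined; matching that
  exactly would require strain-level recovery weights, which default to 1.
* **Read sampling.** `"poisson_split"` (default): independent Poisson
  alternative and reference counts with means $\lambda f$ and
  $\lambda(1-f)$, matching the error model; `"binomial_given_total"`:
  total $\sim \mathrm{Poisson}(\lambda)$, alternative binomial given the
  total; `"expected"`: exact expectations, the noise-free oracle on which
  inference must reproduce truth to $10^{-9}$.
* **Survival assays.** Binomial scoring of `plated_per_day` worms around
  a logistic survival curve per strain and replicate.

Every random draw derives from an explicit seed argument, and the
generator restores the caller's RNG state; count tables are reproducible
byte for byte. The generator does **not** emulate read mapping or variant
calling, restriction-site dropout, PCR duplicates, mapping bias,
density-dependent survival interactions, or strain-by-strain differences
in recovery weight (unless configured). Passing tests on synthetic data
therefore demonstrate correctness of the inference chain under the stated
sampling model, not robustness to those upstream artefacts.

## Numerical and convention choices

* **Quantiles.** `summary_statistics()` uses R's default quantile
  convention (type 7, linear interpolation at index $(n-1)q + 1$), with
  the type exposed as an argument. Conventions matter at panel size:
  on the packaged 96-strain table, type 7 gives median 33.5 and lower
  quartile 21.75 for per-strain marker counts, while order-statistic
  conventions (type 1) give 33 and 21; no standard convention gives
  33 and 22 simultaneously. Reported summaries of such tables should
  state their convention.
* **Variant identity.** Variants are keyed by `(chrom, pos, ref, alt)`
  with 1-based positions; only biallelic SNVs are supported, and no
  strand handling is needed.
* **Tables on disk.** All TSVs are UTF-8, tab-delimited, `.`-decimal,
  with deterministic row ordering (strain, then chromosome/position);
  count tables use `<replicate>_<day>_ref/alt` column pairs.
* **Ties and degeneracies.** Zero day-variance or a single time point
  make a slope impossible and raise an error naming the strain and
  replicate; a strain with no computable slope anywhere is omitted from
  the trait table with a warning, not silently zeroed. Perfect
  association fits floor the p-value at the smallest representable
  positive double so that $-\log_{10} p$ stays finite.
* **Problem sizes in the test suite.** Property tests run at 8–48
  strains, 500–4000 Monte-Carlo replicates, 100 seeds for power-style
  checks and 2000 for test-size calibration — sizes at which the checked
  quantities have comfortably smaller Monte-Carlo error than the asserted
  tolerances, chosen as the package's own verification budget.

## Known limitations

* Frequency estimates are per-strain marginal means; there is no joint
  deconvolution across strains, and shared (non-unique) SNVs are unused.
* The linear slope understates strains with strongly non-linear
  trajectories, and absolute-slope units confound founder frequency with
  selection (see above).
* The logistic parameterisation of survival assumes a single decline;
  biphasic survival curves will fit poorly and should be caught by the
  residual sum of squares in the fit diagnostics.
* The association stage is a naive scan (see above) and the packaged
  96-strain table ships for reproducibility of summary statistics, not
  as a general-purpose genotype resource.
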