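---
title: "Discriminating oesophageal tissue stages from ATR-FTIR spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating oesophageal tissue stages from ATR-FTIR spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirqda)
```

## The problem

Attenuated total reflectance Fourier-transform infrared (ATR-FTIR)
spectroscopy measures tissue absorbance as a function of wavenumber
(cm^-1). In the oesophagus, the progression from normal squamous
epithelium through inflammation, Barrett's metaplasia, low- and high-grade
dysplasia (LGD, HGD) to adenocarcinoma (OAC) leaves subtle biochemical
traces — changes in protein, nucleic-acid, lipid and phosphate absorption
bands — that chemometric classifiers can exploit as an adjunct to
histopathology. This package implements the standard chemometric pipeline
for that task: spectral pre-treatment, three quadratic-discriminant
classification front-ends (PCA scores, SPA- and GA-selected wavenumbers),
Monte Carlo cross-validated figures of merit, bootstrap robustness, and a
synthetic six-class spectra generator that stands in for tissue data that
cannot be redistributed.

## Pre-treatment chain

Raw spectra pass through three steps, per spectrum and in this order:

1. **Fingerprint cut.** The axis is truncated to the closed interval
   [900, 1800] cm^-1. On the default instrument grid (4000 to 600 cm^-1 at
   300/78 ≈ 3.846 cm^-1 spacing, 885 points, consistent with 8 cm^-1
   resolution and 2x zero-filling) this retains exactly 235 wavenumbers.
   The closed interval is deliberate: both endpoints lie on the grid.
2. **Rubber-band baseline correction.** The baseline is the piecewise
   linear curve through the vertices of the lower convex hull of the
   spectrum between its two endpoints — the classical "rubber band
   stretched under the curve". We implement the single-iteration
   convex-hull form with no added support points, which makes the
   operation idempotent, exact for affine baselines, and non-negative in
   its output. Broad concave-down drift components are *not* removed by
   any rubber band; the generator keeps its random drift small enough that
   this residual is minor compared to class differences.
3. **Amide I normalisation.** Each spectrum is divided by its maximum
   absorbance inside [1600, 1700] cm^-1, so the amide I peak height
   becomes exactly 1. We read "normalisation to the amide I peak" as peak
   height rather than band area; the choice is configurable
   (`preprocess_config()`), and since the operation is a positive scalar
   division the downstream classifiers see relative band intensities
   either way. Together with the baseline step this makes the pipeline
   invariant to any positive per-spectrum scaling.

Replicate point spectra (ten per specimen) are preprocessed first and then
averaged per specimen (`average_replicates()`). Modelling per specimen is
the default because the study's confusion matrices count specimens
(35/13/26/4/9/22 per class); a per-replicate analysis is possible by
simply skipping the averaging step.

## Classification models

All three pipelines end in quadratic discriminant analysis (QDA). For a
feature vector $x_i$ the class-$k$ score is

$$Q_{ik} = (x_i-\bar x_k)^{\mathsf T}\Sigma_k^{-1}(x_i-\bar x_k)
  + \log_e |\Sigma_k| - 2\log_e \pi_k,$$

a squared Mahalanobis distance penalised by the class covariance volume
and prior; samples are assigned to the class with the *minimum* score.
Scores are computed through Cholesky factors, never an explicit inverse.
Exact ties (possible in symmetric toy problems) go to the larger prior,
then to the earlier class in the declared order, so predictions are
deterministic.

**Covariance regularisation.** With classes as small as four specimens,
the raw class covariance $\Sigma_k$ is singular for any realistic feature
count. Each class covariance is therefore shrunk toward the pooled
within-class covariance, $(1-\lambda)\Sigma_k + \lambda\Sigma_{pooled}$
with $\lambda = 0.5$ by default, with a trace-scaled ridge fallback should
the result still fail a Cholesky factorisation. This is the smallest
change that keeps the discriminant well defined; $\lambda$ is a visible
argument everywhere. Priors default to empirical class frequencies;
uniform priors are available.

**PCA-QDA** fits mean-centred principal components on the training
spectra and runs QDA on the scores. The component count can be fixed
(`n_components`) or chosen as the smallest count reaching a cumulative
explained-variance target (default 0.935, capped at 6). The analysis
scripts and the reproduction script fix six components — the operating point of
the tissue study this pipeline emulates. The variance-target rule is kept
as the default for data-driven use, but note a caveat found while
validating on synthetic data: when one variance direction dominates (high
separation settings), the target can truncate to a single component and
discard exactly the directions that separate the overlapping classes.

**The selection cost.** Both wavenumber selectors minimise the average
misclassification risk over a validation block,

$$G = \frac{1}{N_V}\sum_{n=1}^{N_V} g_n,\qquad
  g_n = \frac{r^2(x_n, m_{I(n)})}{\min_{I(m)\neq I(n)} r^2(x_n, m_{I(m)})},$$

the squared Mahalanobis distance of each validation spectrum to its own
class mean divided by the distance to the nearest wrong-class mean
(smaller is better). Class means come from the training block only. The
metric defaults to the pooled training covariance on the selected
variables — robust for the four-specimen class — with per-class shrunk
covariances as an option. A validation point exactly at a wrong-class
centre would make the denominator zero; such points get $g_n = \infty$
and are flagged rather than silently dropped. The train/validation block
used *inside* selection is a stratified 70/30 split of the outer training
set, so selection never sees the outer validation specimens.

**SPA-QDA.** The successive projections algorithm builds, for every
candidate starting wavenumber, a chain in which each new wavenumber has
the maximal projection onto the orthogonal complement of the span of the
wavenumbers already chosen (minimal collinearity over the training
samples). Every chain prefix up to `max_vars` is scored with $G$ and the
best (start, length) combination wins. The construction is fully
deterministic; chains cannot repeat an index because a selected column's
residual is zero.

**GA-QDA.** A binary-chromosome genetic algorithm over the wavenumber
axis: fitness is $-G$, tournament selection of size two, single-point
crossover with probability 0.60, per-bit mutation 0.01, elitism of one,
and chromosomes outside the variable-count bounds repaired by random bit
flips. The search runs 100 generations of 200 chromosomes and is repeated
from three independent initial populations, the lowest-$G$ solution
winning — reproducible from a single seed. These operator choices
(tournament, single-point, elitism-1, repair) are the simplest canonical
GA consistent with a fixed-length binary encoding; the four numeric
settings are the study's. The variable-count bound is configurable and
unbounded by default; the analysis scripts bound it at 25, the size of
the selection the tissue study reports.

## Validation machinery

**Monte Carlo cross-validation** (`run_mccv()`): per iteration a
stratified 20% of specimens — `round(0.2 n_k)` per class, never the whole
class — is held out, the *entire* model (PCA or wavenumber selection
included) is refit on the training specimens, and the held-out specimens
are predicted. With the study class sizes the per-iteration held-out
counts are 7/3/5/1/2/4. Refitting selection inside every iteration avoids
information leakage; a `selection_mode = "once"` switch performs selection
a single time on all data, kept only to probe how leakage inflates
figures of merit. Confusion counts accumulated over iterations are
rescaled so each row sums to its class specimen count, using
largest-remainder integerisation (row sums are conserved exactly);
figures of merit are also computed per iteration and reported as mean and
standard deviation.

**Figures of merit**: one-vs-rest sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$ (both percent) and their harmonic-mean F-score
$2\,SENS\,SPEC/(SENS+SPEC)$; overall accuracy is the confusion trace over
the total. Empty denominators yield `NA` ("undefined"), never a silent 0;
the degenerate F-score at $SENS = SPEC = 0$ is defined as 0 and flagged.

**Bootstrap misclassification probability**: specimens are resampled with
replacement within class, the model refit, and out-of-bag specimens
predicted; a specimen's misclassification probability is the fraction of
replicates (in which it was out-of-bag) that got it wrong, and the model
estimate is the mean over specimens. Values above 0.5 signal a model
likely to misclassify in future use.

**Mann–Whitney confirmation**: each selected wavenumber is tested between
a pair of classes with a two-tailed rank-sum test — exact null when both
groups have at most eight specimens and no ties, normal approximation
with tie and continuity correction otherwise (`stats::wilcox.test`
supplies both regimes). P-values are reported raw and flagged at 0.05;
Benjamini–Hochberg adjustment is available but off by default, matching
common practice in this literature.

## The synthetic generator

Real oesophageal tissue spectra are not redistributable, so
`generate_spectra()` builds datasets with the statistical structure the
pipeline assumes. Six Gaussian absorbance bands sit at the wavenumbers the
field assigns to tissue biochemistry — 1745 (lipid ester C=O), 1690
(nucleic-acid carbonyl), 1640 (amide I), 1540 (amide II), 1393 (methylene)
and 1225 cm^-1 (asymmetric phosphate) — with amide I dominant in every
class so the normalisation is well posed, and monotone amplitude trends
across the six ordered stages in the nucleic-acid and phosphate bands.
Per specimen, band amplitudes are drawn log-normally around the class
means (coefficient of variation 0.02); each replicate adds a random slow
polynomial baseline (sd 0.01/0.01/0.005 for offset/linear/quadratic), a
multiplicative gain (sd 0.02) and white noise (sd 0.005 absorbance).

Two knobs shape the class geometry:

* `separation` ($s \ge 0$) scales between-class amplitude ratios
  geometrically: $m = \bar m\,(a/\bar m)^s$ around the across-class mean.
  $s = 0$ erases all class signal, $s = 1$ reproduces the library, larger
  $s$ widens the log-amplitude gaps linearly while amplitudes stay
  positive — which a simple additive scaling cannot guarantee under
  log-normal specimen variation. The library's class amplitudes are
  deliberately subtle (about 1.5–2.5% per stage step) so that even at
  $s = 10$ the absolute amplitudes stay within roughly a factor of two
  and the within-class covariances remain comparable across classes;
  early designs with wider library spreads produced order-of-magnitude
  variance heterogeneity at high separation, which defeats pooled
  covariance shrinkage and misleads the $G$ metric.
* `overlap` ($o \in [0,1]$) moves the normal and inflammatory amplitude
  means toward their midpoint, coinciding at $o = 1$.

The defaults are the study conditions: class sizes 35/13/26/4/9/22, ten
replicates, $s = 5$, $o = 1$. Under them the two earliest stages are
spectrally confusable while Barrett's, LGD, HGD and OAC separate cleanly —
the qualitative structure the tissue study reports, with misclassification
confined to the normal/inflammatory block of the confusion matrix.

What the generator does *not* emulate: ATR physical optics (penetration
depth, scattering), paraffin/deparaffinisation residuals, water vapour and
CO2 lines, correlated instrument drift across replicates, and real
inter-replicate variance (unreported for the tissue data; it is a free
parameter here). Passing tests on synthetic data therefore demonstrate
correctness and internal consistency of the algorithms, not clinical
performance on real tissue.

## Numerical choices and degenerate inputs

* Closed-interval wavenumber selection uses a tolerance of 1e-6 of the
  median grid spacing, so interval ends that are exact in rational
  arithmetic are not lost to floating-point representation.
* Covariances are symmetrised before factorisation; the ridge fallback
  starts at 1e-8 of the mean diagonal and escalates tenfold until the
  Cholesky succeeds.
* An all-constant spectrum fails amide normalisation with a
  degenerate-spectrum error; a class with one specimen and $\lambda = 0$
  fails with advice to set $\lambda > 0$; a Monte Carlo plan whose
  hold-out rounds to zero everywhere is rejected.
* Classed conditions (`ftirqda_*_error`) distinguish label, axis, format,
  interval, plan, singularity and configuration failures.

## Problem sizes in the bundled runs

The analysis scripts and the reproduction script
(`scripts/acceptance.R`) use 100 Monte Carlo
iterations, 100 bootstrap replicates and a reduced in-loop GA (15
generations x 40 chromosomes, one restart, 2–8 variables) — sizes chosen
so a complete desk rerun of every script finishes in minutes while leaving
the Monte Carlo standard errors on reported figures of merit below about
one percentage point. The full study settings (1000 iterations; GA
100 x 200 x 3) are plain arguments away and are exercised at full strength
where they are cheap: the GA correctness test runs 100 x 200 x 3 on an
eight-feature problem against an exhaustive-search oracle.

## Known limitations

* The published headline numbers for the real tissue data (90.9/86.4/63.6%
  accuracies, 0.322/0.311/0.181 bootstrap probabilities, 93.5% variance on
  six PCs) depend on spectra that are not publicly deposited; nothing here
  can or does reproduce them, and the synthetic defaults are tuned to the
  qualitative structure, not those values. Relatedly, the printed per-class
  specificities are not all consistent with the printed average confusion
  matrices, so only row-determined quantities are used as worked examples.
* QDA regularisation, priors, and the covariance behind the Mahalanobis
  metric in $G$ are unstated in the source literature; the defaults here
  ($\lambda = 0.5$ to pooled, empirical priors, pooled metric) are logged
  choices, not reconstructions.
* The rubber band cannot remove concave-down baseline drift (inherent to
  the method, not this implementation).
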