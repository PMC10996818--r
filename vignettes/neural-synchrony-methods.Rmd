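---
title: "Methods: group-level neural synchrony for fNIRS naturalistic paradigms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-level neural synchrony for fNIRS naturalistic paradigms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosync)
```

## Overview

`neurosync` implements a complete analysis chain for group-level neural
synchrony under emotional naturalistic stimulation, as measured with
functional near-infrared spectroscopy (fNIRS): preprocessing from raw
dual-wavelength light intensities to standardised total-haemoglobin channel
time courses; intersubject correlation (ISC) with permutation inference;
intersubject representational similarity analysis (IS-RSA) under
Nearest-Neighbor and Anna-Karenina similarity models; and two-part
zero-inflated Gaussian mixed models for bounded 0--100 emotion ratings.
Because raw human recordings of this kind are rarely shareable, the package
also contains a first-class synthetic-data module that generates cohorts,
raw optical intensities, and rating tables with the statistical structure
the analyses assume. Every downstream stage is exercised and tested against
these generators.

## The shared-response model

The generative model for a subject's channel time course is the standard
shared-response decomposition

$$X_A(t) = \alpha_A\, C(t) + \beta_A\, \mathrm{id}_A(t) + \varepsilon_A(t),$$

where $C(t)$ is a stimulus-locked component common to all subjects,
$\mathrm{id}_A(t)$ is idiosyncratic structured activity independent across
subjects, and $\varepsilon_A(t)$ is white measurement noise. Both $C$ and
$\mathrm{id}_A$ are generated as unit-variance stationary processes, so the
expected Pearson correlation between two subjects is
$\alpha_i \alpha_j / \sqrt{(\alpha_i^2+\beta_i^2+\sigma^2)
(\alpha_j^2+\beta_j^2+\sigma^2)}$; with $\alpha = \sigma = 1$ and
$\beta = 0$ this equals $1/2$, a closed form the test-suite checks by
simulation.

The default $C(t)$ is Gaussian noise low-pass filtered below 0.5 Hz and
standardised — a stationary process confined to the hemodynamic band.
The spectral content of real stimulus-evoked responses is not known in
detail; any unit-variance stationary process in this band would serve, and
a band-limited random-phase sinusoid mixture is available as an
alternative (`shared_signal_kind = "band-limited"`).

### Behaviour-coupled cohorts

Two coupling structures link synchrony to a per-subject behavioural score
(a 0--100 emotion-reactivity rating):

* **Anna Karenina (`annak`)** — high scorers synchronise, low scorers are
  idiosyncratic. The shared weight becomes
  $\alpha_A + \kappa\,(\mathrm{rank}(s_A) - 0.5)/n$: monotone in rank,
  bounded, and reducing to uniform weights under ties.
* **Nearest Neighbor (`nn`)** — similarity tracks score *proximity*
  anywhere on the scale. Subjects receive latent signals with
  cross-subject correlation $\exp(-|s_i - s_j|/\ell)$ (a Gaussian-process
  kernel along the score axis; $\ell$ is exposed as `length_scale`,
  default 20 rating points), scaled by $\kappa$ and added to the base
  cohort.

Setting $\kappa = 0$ (or `structure = "none"`) reproduces the base cohort
*bit for bit*: the generator consumes identical random draws regardless of
the weights, so coupling changes amplitudes, never realisations.

## Preprocessing chain

The chain runs in a fixed order, recorded in the output provenance:
trim/concatenate by condition, channel quality control, zero-phase bandpass
filter, PCA motion correction (all on optical signals), conversion to
haemoglobin concentrations by the Modified Beer--Lambert Law (MBLL), and
per-channel standardisation of total haemoglobin (HbO − HbR).

Choices the underlying study description leaves open, fixed here as
package defaults (all overridable):

* **Filter** — order-3 Butterworth high-pass (0.005 Hz) and low-pass
  (0.5 Hz) stages applied forward and backward (`filtfilt`), so no group
  delay. Cascading two stages keeps the recursion stable at the very low
  normalized high-pass edge; the series is demeaned first, which removes DC
  exactly. Only the band is prescribed by common fNIRS practice; the family
  and order are package choices.
* **Channel QC** — a channel is unusable if detector saturation (samples at
  or above 99% of the ADC ceiling by default) persists for *more than* 2 s
  (a run of exactly 2 s is still usable), or if its spectrum is as flat as
  white noise: the quartile coefficient of dispersion
  $(Q_3-Q_1)/(Q_3+Q_1)$ of the one-sided PSD falls below 0.1. The PSD is a
  Welch-style averaged periodogram (24-sample 50%-overlap rectangular
  segments, DC bin excluded). The segment length was fixed once from the
  estimator's sampling behaviour: heavy averaging makes the white-noise
  QCoD distribution concentrate well below 0.1 while genuinely structured
  spectra stay far above it. QC only flags channels; it never modifies
  data.
* **PCA motion correction** — principal components of the channel × time
  matrix are removed in variance order until the removed set first reaches
  `variance_fraction` (default 0.8, typical of PCA artifact-reduction
  routines in fNIRS toolboxes); at most $n_\mathrm{channels}-1$ components
  are ever removed, and a fraction of 0 removes nothing.
* **MBLL** — differential pathlength factor 6.0 at both wavelengths and
  extinction coefficients at 760/850 nm from the standard compiled
  absorption tables, both overridable. The default baseline intensity is
  the temporal *geometric* mean per channel and wavelength: in
  optical-density units this is the plain mean, and it recovers the true
  baseline exactly when concentration changes average to zero, making the
  forward-model round trip exact to numerical precision. Non-positive
  intensity samples are excluded from the baseline and returned as `NA`.
* **Standardisation** — the total-haemoglobin signal is z-scored per
  channel with the population (1/T) denominator, so that the squared
  Euclidean distance between two standardised time courses of length $T$
  equals $2T(1-r)$ *exactly* — the identity that ties the ISC and IS-RSA
  similarity representations together and is verified to 1e-8 in the
  acceptance suite.

## Intersubject correlation and permutation inference

Pairwise ISC is the Pearson correlation between two subjects' channel time
courses. Leave-one-out ISC correlates each subject with the *mean* of all
others; because averaging suppresses noise in the reference, leave-one-out
values systematically exceed mean pairwise values on shared-response
cohorts (verified by simulation). All ISC computations standardise each
subject first, so results are invariant to per-subject affine rescaling.

The two-sample statistic tests $H_0: \mathrm{ISC_{within}} =
\mathrm{ISC_{between}}$: within-group synchrony is the mean leave-one-out
ISC inside each group; between-group synchrony is each subject's
correlation with the *full* mean time course of the other group
(leave-one-out has no natural "leave" across groups); the statistic is
their difference, one-sided for within > between by default, matching the
directional hypothesis of group-specific encoding. The null is built by
subject-wise permutation: random reassignment of subjects to groups with
group sizes preserved. Relabelings that reproduce the observed grouping
are excluded and redrawn, so a maximal observed effect attains the minimal
p-value $1/(n_\mathrm{perm}+1)$; the add-one rule keeps p strictly
positive everywhere. Internally the statistic is evaluated from the Gram
matrix of standardised time courses, making each permutation $O(n^2)$
regardless of recording length.

For a single group there is no relabeling to permute, so the one-sample
test uses a different null with the same target (false-positive-rate
control): each subject's time course is independently circularly shifted
by a random non-zero offset, which preserves autocorrelation while
destroying time-locked alignment. This scheme is a replacement for the
(undescribed) one-sample construction in the source methodology, not a
reproduction of it. Both nulls are calibrated in the test suite: under
independent-noise cohorts the two-sample test rejects at $0.056$ and the
one-sample test at $0.065$ at nominal $\alpha = .05$ (500 and 200
Monte-Carlo repetitions respectively).

## IS-RSA: Nearest-Neighbor vs Anna-Karenina models

The Nearest-Neighbor behavioural representation is the squared Euclidean
distance between scores, $D_{ij} = (s_i - s_j)^2$; the Anna-Karenina
representation is the mean-rank similarity $(\mathrm{rank}_i +
\mathrm{rank}_j)/(2n)$ with average-rank ties, invariant to any strictly
increasing transform of the scores. Neural similarity is the pairwise ISC
matrix (the $2T(1-r)$ identity links it to time-course Euclidean
distances, so both readings of "similarity matrix" coincide up to a
monotone transform on standardised data).

Before correlating, distances are negated so that both matrices are
oriented "higher = more similar". The IS-RSA statistic is the Spearman
correlation of the strictly-upper triangles (Spearman is the convention in
IS-RSA work; Pearson is exposed). Inference jointly permutes rows and
columns of the behavioural matrix under random subject relabelings
(identity excluded), two-sided on $|r|$ by default. The Mantel test is the
same machinery with a linear correlation, one-sided by default, and is
cross-checked in the tests against an independent implementation
(`vegan::mantel`).

Model comparison runs both models on every channel and compares the two
per-channel fit vectors with a paired t-test; a perfectly consistent
non-zero difference (zero variance) is reported via a flag rather than a
meaningless p-value. On synthetic cohorts with known coupling the
comparison recovers the generating structure in 100/100 seeds in each
direction (n = 30 subjects, 5 channels, 200 time points, coupling
strengths 2.5 for AnnaK and 1.5 for NN — "strong" couplings fixed before
the comparison was run).

A per-subject behavioural score is taken as the subject's mean rating of
the target emotion over experimental videos; other aggregates (max,
change scores) would slot in identically.

## Two-part models of bounded emotion ratings

Ratings on a 0--100 slider pile up at the intense extreme (100 for
negative emotions, 0 for joy). The transformation
$t = \ln(101 - \mathrm{raw})$ for negative emotions and
$t = \ln(\mathrm{raw} + 1)$ for joy maps the scale to $[0, \ln 101]$ with
the extreme landing exactly at $t = 0$; these are the unique reflection/
shift constants for a 0--100 scale under the recipe "recalibrate so the
minimum is 1, then take logs". The transform is a bijection and its
inverse is provided. Fear, which shows neither skew nor boundary
inflation, passes through untransformed and is modelled by a single REML
linear mixed model.

The two-part model splits the data at $t = 0$:

* a **logistic mixed submodel** of the indicator "non-extreme" on
  time, group, and their interaction, with a subject random intercept.
  Success is coded as *non-extreme*, so an odds ratio below 1 on the
  time-by-group interaction reads as "more extreme responses after
  training in the treated group". Odds ratios are exactly
  $\exp(\hat\beta)$ with Wald intervals exponentiated from the link scale.
* a **Gaussian linear mixed submodel** of $t$ on the non-extreme rows,
  same fixed and random structure, fitted by maximum likelihood.

Estimation uses `lme4`: adaptive Gauss--Hermite quadrature with 25 points
for the logistic submodel (with a single scalar random effect this is
cheap, and it gives noticeably better-calibrated Wald intervals than the
Laplace approximation when the intercept variance is large — coverage
0.90--0.96 versus 0.64--0.72 in the package's recovery simulations), ML
for the Gaussian submodel, REML for the fear model. Acceptance is by
parameter recovery, not estimator identity with any particular package:
across 50 replicate cohorts of 72 subjects × 16 ratings at the default
generator coefficients, the 95% Wald intervals of all eight fixed effects
cover the truth at rates between 0.90 and 0.98.

Variance components are summarised by the intraclass correlation
$\tau_{00}/(\tau_{00} + \sigma^2)$, with $\sigma^2 = \pi^2/3$ on the
latent logistic scale, and by marginal/conditional $R^2$ computed from the
variance of the fixed-effect linear predictor over the estimation sample
(the standard variance-partition definition; whether to compute it on the
observed or transformed scale is a genuine ambiguity — the linear-predictor
definition on the modelling scale is used). These satisfy
$R^2_\mathrm{cond} = R^2_\mathrm{marg} + (1 - R^2_\mathrm{marg})
\cdot \mathrm{ICC}$ identically.

The rating *generator* is the exact generative twin of this model: a
logistic draw for "non-extreme" (subject intercept included), then a
Gaussian draw on the transformed scale clamped to $(0, \ln 101]$ and
back-transformed. Its default coefficients place the Gaussian submodel at
the anger column of the fitted-variance scale reported for this design
(intercept 2.78, residual sd 0.62, subject-intercept sd 0.57) and give the
logistic submodel a strong negative time-by-group interaction
($-2.1$, i.e. an odds ratio of about 0.12) with subject-intercept sd 1.8;
the fear generator uses the published fear-model components (intercept
51.6, $\sigma^2 = 333.9$, $\tau_{00} = 492.8$) on the raw scale, truncated
to 0--100.

```{r icc-example}
# worked variance-component arithmetic
icc_gaussian(0.28, 0.35)   # Gaussian submodel ICC
icc_logistic(4.27)         # logistic submodel ICC on the latent scale
r2_nakagawa(0.010 * (0.28 + 0.35) / (1 - 0.010), 0.28, 0.35)
```

Group differences in attitude-style outcomes are tested with the
Mann--Whitney U test: U from rank sums with average-rank ties, exact
enumeration when $n_a n_b \le 400$ without ties, otherwise the
tie-corrected normal approximation with continuity correction.

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure* the analyses assume:
shared versus idiosyncratic temporal components, score-coupled similarity
structures, boundary-inflated bounded ratings with subject-level
clustering, and the optical forward model for MBLL round trips. They do
not emulate physiological nuisance structure — no scalp or systemic
components, no Mayer waves, no cardiac or respiratory peaks, no motion
spikes beyond the explicit artifact injectors — and the spectral content
of the shared signal is a modelling choice, not an empirical fact. Tests
passing on these cohorts therefore validate the *inferential machinery*
(calibration, power against known structure, exact arithmetic), not
performance on any particular real recording.

## Numerical and design notes

* Every stochastic function takes an explicit integer seed and restores
  the caller's RNG state; identical seed and spec give bit-identical
  output, which the pipeline uses to guarantee byte-identical reruns.
* Permutation p-values use the add-one rule and so never return 0; the
  identity relabeling is excluded from every permutation null.
* Degenerate inputs fail loudly: all-tied scores make the Anna-Karenina
  matrix constant and are rejected; constant time courses are excluded
  from ISC with a warning; constant HbO − HbR channels are dropped; a
  constant group or time indicator is a rank-deficiency error; a design
  with one observation per subject is flagged as non-identifiable.
* A channel-count threshold sometimes quoted alongside per-channel
  significance (a minimum-extent rule) is not implemented: its definition
  is not available, and per-channel false-positive control is the
  documented guarantee.
* Problem sizes used by the acceptance suite: 500 Monte-Carlo repetitions
  × 1000 permutations at n = 8+8, T = 500 for false-positive calibration;
  100 seeds per direction at n = 30 for model-structure recovery; 50
  replicates of 72 × 16 ratings for coefficient recovery. These sizes give
  Monte-Carlo standard errors comfortably inside the asserted bands.
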