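---
title: "Methods: spatial capture-recapture from non-invasive genetic sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial capture-recapture from non-invasive genetic sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxscr)
```

## The problem and the model

`foxscr` estimates the density of an elusive carnivore from non-invasive
genetic sampling (NGS): scat, urine and hair samples collected along winter
transects, genotyped to individual, and snapped to a grid of "detectors" (the
centres of 500 x 500 m cells tiling the searched area).  The statistical core
is a maximum-likelihood spatial capture-recapture (SCR) model.

SCR is a hierarchical model with two submodels:

* **Density.**  Individual activity centres (ACs) follow an inhomogeneous
  Poisson point process over a discretized *state space* - the searched area
  plus a buffer wide enough to contain the AC of any individual exposed to
  sampling (the buffer rule is 4 x the largest space-use scale).  The
  intensity in cell $g$ is $\mu(g) = \exp\{\beta_0 + \sum_k \beta_k x_k(g)\}$
  individuals per km^2; available covariates are a session (year) intercept
  and neighbourhood-averaged forest cover.
* **Detection.**  Given an AC at $s$, the count of an individual's samples at
  detector $j$ is Poisson with rate
  $\lambda_j(s) = \lambda_0(j)\, e^{-d(s,j)^2 / 2\sigma^2}$: a half-normal
  kernel in the AC-detector distance with baseline rate $\lambda_0$ (log
  link; covariates: session, search effort, road length, forest cover, sex)
  and scale $\sigma$ (log link; covariate: sex).

Because samples are season-aggregated counts per detector rather than
occasion-structured binary captures, the encounter model is a Poisson count
model; the baseline parameter is therefore an encounter *rate*, not a
per-occasion probability.  Signs and significance of covariate effects are
directly comparable to binomial-SCR parameterisations, but the numeric value
of the baseline is not, and no occasion count is needed.

Sex enters detection and scale jointly or not at all: the two parameters
trade off against each other, so a sex effect estimated on only one of them
is not interpretable.  The sex of every *detected* individual is known (a
genetic sex assay), but the sexes of undetected individuals are not, so the
model carries a mixture proportion $\psi$ (proportion male, logit link).
$\psi$ and the per-individual sex-membership terms are included in **every**
model, including those without sex effects (where $\hat\psi$ reduces to the
observed sex ratio).  This keeps all candidate models likelihoods of the
same data - counts *and* sexes - so AIC comparisons and nested log-likelihood
orderings remain valid across the candidate set.

The marginal log-likelihood of one session, summing over AC cells and using
the known sex $c_i$ of each detected individual, is

$$
\log L = \sum_{i=1}^{n} \log\Big[\psi_{c_i} \sum_g \mu(g)\,a
  \prod_j \mathrm{Pois}(y_{ij};\lambda_j(g, c_i))\Big] - \bar\Lambda,
\qquad
\bar\Lambda = \sum_c \psi_c \sum_g \mu(g)\,a\,p_\cdot(g, c),
$$

where $a$ is the cell area and $p_\cdot(g,c) = 1 - e^{-\sum_j \lambda_j(g,c)}$
is the probability of at least one detection.  $\bar\Lambda$ is the expected
number of *detected* individuals, so $-\bar\Lambda$ accounts for the
individuals never seen.  Sessions are independent; session terms give each
session its own intercepts while slopes are shared.  The heavy inner sums
(a detectors-by-cells kernel matrix per sex) are evaluated in compiled
C++ (RcppArmadillo) with log-sum-exp stabilisation; the distance matrix and
the count cross-products are precomputed once per fit.

## Genotyping module

Replicate-consensus calling follows the standard NGS protocol: three PCR
replicates per sample and marker; a homozygote is accepted only when all
three replicates agree, a heterozygote when at least two replicates are the
same heterozygote; anything else is missing.  The per-sample quality index
(QI) is the proportion of replicate calls (over all markers jointly) that
match the marker's consensus; markers without consensus, and failed
replicates, count as inconsistent.  Samples with QI >= 0.70 are retained.
Two conventions the protocol leaves open are resolved as follows:

* QI is computed over all replicate calls jointly rather than as a
  per-marker average; the two coincide when no data are missing, and the
  joint form is the more conservative reading of "proportion of consistent
  gene scores".
* The sex assay is a determination test, not a scored genotype, so it is
  excluded from QI and identity matching.

Identity assignment (`match_individuals()`) is a deliberately simple greedy
clustering - samples in ascending ID order join the first cluster whose
exemplar disagrees at no more than `max_mismatch` scored markers.  It is a
placeholder for dedicated multilocus-matching software (e.g. Allelematch),
adequate for simulated data and exact when genotyping error is absent; it is
**not** a probabilistic matcher and should not be used on real data with
appreciable error rates.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the statistical structure the estimator assumes:

* a forest-cover surface built from moving-average-smoothed white noise,
  min-max rescaled to [0, 1] - the simplest field with a controllable
  correlation length (`forest_smoothness`, km);
* roads and search tracks as jittered edge-to-edge polylines; per-detector
  search effort and road length are the polyline length within each detector
  cell (computed by dense sampling along segments, step = cell side / 20);
* ACs drawn from the inhomogeneous Poisson process (continuous positions,
  uniform within the sampled cell, so detector snapping and discretization
  are genuinely exercised), sexes Bernoulli($\psi$);
* Poisson counts from the half-normal model; undetected individuals are
  reported in a separate truth record and never reach the fitting code;
* triplicate genotypes with allelic dropout and false-allele errors applied
  to per-individual true genotypes.

It does **not** emulate weather-driven DNA degradation, sample-type-specific
amplification success, GPS-track measurement error, temporal clustering of
visits, or non-circular home ranges.  Passing the recovery tests therefore
shows the estimator is correct *under its own assumptions*, not that those
assumptions hold in any particular field system.

Defaults mirror the study design the package is modelled on: two 15 x 15 km
study areas, 500 x 500 m detector cells (900 detectors), 14 microsatellite
markers with three replicates, a 0.70 QI threshold, winter sessions treated
as independent years.

## Fitting, tolerances and numerical choices

* Covariates are z-scored internally (detector covariates pooled over
  sessions; state-space covariates over cells) for optimizer conditioning;
  means and SDs are stored in the fit so predictions are on the raw scale.
  A test asserts the maximized log-likelihood is invariant to this choice.
* Optimizer: BFGS with `reltol = 1e-10` (default) and numerically
  differentiated gradients.  A fit is declared converged when `optim`
  reports success and the central-difference gradient norm at the optimum is
  below 0.1 - on a log-likelihood of magnitude ~10^3 with curvature of order
  the sample size, that bounds the parameter error well below Monte-Carlo
  noise; demanding much smaller finite-difference gradients is not
  meaningful at double precision.
* Default starts: density intercept at the naive detected density
  $\log(n/\text{area})$; $\log\sigma$ at an eighth of the grid span;
  baseline rate spreading the mean per-individual count over the effective
  number of exposed detectors $2\pi\sigma_0^2/a$; slopes at zero; $\psi$ at
  the observed sex ratio.  A non-finite likelihood at the start triggers one
  fallback start; persistent failure raises a classed error, never a silent
  result.
* Uncertainty: inverse observed information (numerical Hessian) at the MLE;
  Wald intervals on the link scale, back-transformed; abundance intervals by
  the delta method on the log scale (the interval method for abundance is a
  package choice; the source analysis does not state one).
* Ties in the AIC table break toward fewer parameters, then model label;
  non-converged candidates are excluded with a warning rather than an error,
  matching candidate-screening practice.
* Equidistant samples snap to the lowest detector index; the buffer is a
  rectangular expansion snapped up to a whole number of cells.
* Parameter counts include $\psi$ and one intercept per session per
  submodel; software that codes session effects differently will report
  different counts for the same model, which affects no within-package
  comparison.

## Derived quantities

* **Home range.**  Under the implied bivariate-normal space use, the area
  holding fraction $q$ of the utilization distribution is
  $\pi \sigma^2 \chi^2_q(2)$; at $q = 0.95$ the quantile is 5.9915 (computed
  by `qchisq()`, never hard-coded).  Interval bounds for $\sigma$ are passed
  through the same transform.
* **Expected density / abundance.**  $\hat\mu(g)$ per cell;
  $\hat N(R) = \sum_{g \in R} \hat\mu(g) a$ for any rectangular region.
* **Realized density.**  Each detected individual contributes its posterior
  AC distribution (Bayes' rule over cells); undetected individuals
  contribute $\sum_c \hat\psi_c \hat\mu(g) a (1 - p_\cdot(g,c))$.  The
  surface totals `n detected + expected undetected` exactly, which is
  asserted in tests.

## Validation design and problem sizes

Correctness is checked along two independent routes: every likelihood and
posterior computation is compared, on instances with at most 9 state cells,
3 detectors and 3 individuals, against a plain-R enumeration oracle written
directly from the formula above (agreement to 1e-10); and the full pipeline
is validated by simulation at a reduced but realistic scale chosen to keep
the default test run within ordinary desk budgets:

* **Parameter recovery**: 900 detectors, forest-dependent density
  (coefficient 2 on the z-scored covariate) with ~60 expected ACs in the
  searched 225 km^2, sex-structured detection ($\sigma$ = 1.6 / 2.0 km,
  baseline rate giving a few detections per detected individual), analysis
  state space at 1 km resolution inside the 8 km buffer; 25 replicates.
  Mean estimates must fall within 3 Monte-Carlo standard errors of truth and
  pooled 95% Wald coverage within [88%, 99%].
* **Model selection**: the 16-model candidate set refitted on the first 5
  recovery replicates using a coarser 1.5 km screening mask; the generating
  model must rank first by AIC in the majority.

The 1 km analysis mask (rather than the 0.5 km data grid) and the 25/5
replicate counts are deliberate problem-size choices; a separate test
asserts the likelihood is invariant to state-space refinement, which is what
justifies the coarser mask.

## Known limitations

* Closed-population, single-season inference only; no open-population
  dynamics, no behavioural response, no telemetry integration, no
  unidentified-sample augmentation.
* Discrete-space marginalisation only; accuracy is governed by the mask
  resolution relative to $\sigma$.
* The greedy identity matcher is a stand-in (see above).
* Planar km coordinates in a local frame; no projection management.
* The rectangular buffered state space does not reproduce irregular,
  transect-shaped habitat masks.
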