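---
title: "Benchmarking cell type-specific differential expression from bulk deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell type-specific differential expression from bulk deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdebench)
```

## The problem and the model

Bulk transcriptomes of mixed tissues confound two sources of between-group
change: shifts in cell type composition and shifts in expression within
cell types. When the composition is known, the second source — cell
type-specific differentially expressed genes (csDEGs) — can in principle be
recovered from bulk data alone. `csdebench` provides a controlled
environment for asking *how well*: it simulates bulk mixtures whose
cell type-specific truth is known exactly, runs a family of csDEG
detectors on them, and measures what survives.

Everything rests on the linear mixing model

$$E_{ij} \;=\; \sum_{t \in T} C_{tj} \, S^{j}_{it},$$

where $E$ is the observed bulk matrix (genes $\times$ samples), $C$ the cell
type proportion matrix (cell types $\times$ samples, columns on the
simplex), and $S^{j}$ the per-sample cell type-specific expression profiles
(csGEPs). Because $S$ is defined per sample, it is a genes $\times$ cell
types $\times$ samples tensor in the simulator; detectors only ever see $E$
and $C$.

## The semi-simulation engine

The generator emulates the statistical structure of semi-simulated
benchmarks built from sorted-cell and single-cell compendia: blood-like
mixtures of 4–6 cell types with unequal mean proportions (rare types down
to a few percent), per-sample profiles with substantial between-individual
heterogeneity, and two groups of 100 samples each (group sizes this large
are needed because expression deconvolution estimates one parameter per
cell type per gene per group).

Each piece is drawn as a clipped normal:

* **Proportions.** Per sample, raw abundances are drawn
  $\mathcal N(\mu_t, \sigma_t)$ per cell type, negatives are set to 0 and
  the column is rescaled to sum to one. A column that is all zero after
  clipping is redrawn (at most 100 times) rather than divided by zero. The
  default benchmark model uses mean proportions $(0.2, 0.35, 0.25, 0.2)$
  with $\sigma_t = \mu_t/2$ — a proportion CV of 0.5, comparable to the
  sample-to-sample spread of measured blood compositions.
* **Profiles.** $S^{j}_{it} \sim \mathcal N(m_{it}, s_{it})$, clipped at 0.
  Expression is non-negative, so clipping is applied to profiles as well as
  proportions; it is toggleable (`clip_negative`) because at large CVs the
  clipped normal is visibly skewed and one may want the raw draws.
  `random_profile_model()` draws gene means log-normally (meanlog 4,
  sdlog 1, i.e. typical means of ~55 expression units with a heavy right
  tail) and gene-wise CVs uniformly in $[0.4, 0.95]$, the range of median
  CVs observed across sorted blood cell types.
* **Heterogeneity control.** `cv_override` pins the coefficient of
  variation: for an overridden cell type the sampling sd becomes
  $\mathrm{cv} \cdot m_{it}$ for every gene, while the mean stays at its
  modelled level. The sd is tied to the *control* mean so that injected
  fold changes alter the signal, not the noise.
* **csDEG injection.** Per cell type, $\lceil f \cdot G \rceil$ genes are
  chosen uniformly; their case mean is the control mean times a fold change
  drawn uniformly from a range (default $[1.5, 3]$), direction up or down
  with probability $\tfrac12$. The defaults (10% of genes, fold changes
  1.5–3) give a signal that is clearly detectable at low heterogeneity and
  progressively lost as CV grows, which is the regime the benchmark is
  designed to map. The injected mask is kept as ground truth, but scoring
  uses a *detectability-aware* gold standard (below).
* **Outlier samples.** Appended samples whose profile means sit at the
  Tukey limits of the base samples' profiles: per cell type one side is
  chosen at random, the gene-wise mean is $Q_1 - 1.5\,\mathrm{IQR}$ or
  $Q_3 + 1.5\,\mathrm{IQR}$ (quartiles by linear interpolation, type 7 —
  quartile conventions differ, so this is stated explicitly), clipped at 0,
  and the profile is drawn with the gene's original sd. Proportions come
  from the same proportion model as everyone else: these are samples whose
  *profiles*, not compositions, are aberrant, which is exactly the kind of
  outlier that bulk-level screening cannot see.
* **Unknown-cell noise.** Optionally, $k \sim \mathrm{Uniform}\{10..100\}$
  expression vectors of an unmodelled cell type are summed into each bulk
  column, scaled by `per_cell_scale` (default 1/500, one cell of a nominal
  500-cell sample) so that tens of unknown cells perturb rather than
  dominate. $C$ is deliberately not updated — the noise stays unknown to
  the detectors.
* **Gene filter.** Genes whose median bulk expression is zero in both
  groups are dropped last, and the kept-gene mask is recorded.

All randomness passes through explicit integer seeds; `simulate_dataset()`
derives stage-wise sub-seeds from one master seed and is bit-reproducible.

### What the generator does not emulate

Draws are (clipped) normals on a continuous expression scale: there is no
count noise, no library-size variation, no normalisation artefacts, no
technical batch structure, and no correlation between genes beyond what the
mixing itself induces. Passing benchmarks here therefore show how detectors
cope with *composition, heterogeneity and contamination* — not with
count-model misspecification. Detectors built around negative-binomial
count likelihoods are out of scope for the same reason.

## Deconvolution cores

All cores fit each gene independently against the shared design
$X = C^\top$ with no intercept ($C$'s columns sum to one, so an intercept
would be exactly collinear).

* `ols_fit()` — ordinary least squares via one QR decomposition for all
  genes; classical standard errors with $n - T$ degrees of freedom.
* `nnls_fit()` — the same objective under $s_t \ge 0$ (Lawson–Hanson active
  set in compiled code, entered only for genes whose unconstrained optimum
  is infeasible). Exact inference under the constraint is not available;
  standard errors are taken from the unconstrained fit restricted to the
  positive coordinates and flagged approximate (`NA` at clamped
  coordinates). Detectors built on this core rely on permutation, not on
  these standard errors.
* `robust_fit()` — per-gene Huber M-estimation by IRLS, with tuning
  constant 1.345 (the classical 95%-efficiency choice) and the residual
  scale re-estimated each iteration as $\mathrm{median}|r|/0.6745$.
  Convergence is declared when the largest coefficient change falls below
  `tol` *relative* to the coefficient magnitude
  ($\max|\Delta b| / \max(1, \max|b|) < 10^{-8}$): an absolute criterion is
  meaningless across expression scales of $10^0$–$10^4$. Unconverged genes
  (cap 50 iterations) keep their final iterate and are flagged with a
  warning. The IRLS lives in C++ because the permutation recipe refits
  every gene a thousand times; the implementation is cross-checked against
  `MASS::rlm` in the test suite.

## csDEG detectors

All detectors return one tidy row per (gene, cell type) with an effect
size, a statistic, a p-value and a BH-adjusted FDR. BH is applied within
each cell type by default (each cell type is reported as its own family);
pooling across cell types is available behind a flag.

* **Permutation recipe** (`permutation_detector()`): deconvolve case and
  control samples separately with any core, take the absolute difference
  per (gene, cell type), then repeat under $n$ random reshuffles of the
  group labels (group sizes preserved) and report $p = m/n$, where $m$
  counts permuted differences strictly exceeding the observed one. $p = 0$
  is therefore possible; an optional $(m+1)/(n+1)$ correction is provided
  but off by default, keeping the estimator exactly as defined. Ties count
  as not exceeding, and the comparison carries a $10^{-9}$ relative guard
  so that refits differing only by floating-point rounding (e.g. the
  observed labeling re-encountered in another column order) register as
  ties. The strictly-greater convention biases p slightly downward at
  ties; with continuous statistics this is negligible.
* **Welch detector** (`welch_detector()`): the closed-form shortcut for
  the OLS core — $t = (\hat s_{\mathrm{case}} - \hat s_{\mathrm{control}})
  / \sqrt{se^2_{\mathrm{case}} + se^2_{\mathrm{control}}}$ with
  Welch–Satterthwaite degrees of freedom. Edge rule, stated because zero
  standard errors do occur in noiseless simulations: both se zero and zero
  difference gives $p = 1$; zero se with a nonzero difference gives
  $p = 0$.
* **Interaction detector** (`interaction_detector()`): one linear model
  per gene over *all* samples with $2T$ covariates — the proportions and
  their products with the case indicator — and a t-test on each
  interaction coefficient, whose estimate is exactly the case − control
  expression difference for that cell type.

Under the null the permutation detectors are calibrated by construction
(exchangeability); the two closed-form detectors assume homoskedastic
errors that the mixture model mildly violates (the error variance of
$E_{ij}$ given $C$ is $\sum_t C_{tj}^2 s_{it}^2$, which varies across
samples), so their type-I error sits slightly above nominal but inside the
accepted band in the calibration tests.

## Residual diagnostics

Users of real data cannot see the profile heterogeneity that drives
detector accuracy, but they can see its footprint in the residuals. The
summary statistic is

$$\mathrm{median}_{G}\big(\mathrm{median}_{R}\,|E_G - \hat S_G C| / E_G\big),$$

the median over the `n_top` (default 10000) highest-median-expression
genes of the per-gene median over samples of the reconstruction error
relative to the bulk. Relative residuals make the statistic invariant to
the overall expression magnitude (hence to normalisation scale); the
top-expression filter keeps near-zero denominators out. Entries with
$E_{ij} = 0$ are excluded from the medians (the division is undefined); a
selected gene that is zero in every sample is dropped with a warning. When
group-wise estimates are supplied, each sample is reconstructed with its
own group's $\hat S$ (single-estimate mode is available for parity with
tools that output one residual matrix).

Guidance bands, calibrated against the benchmark's accuracy-vs-residual
sweeps: below 0.15 the diagnostic is consistent with good accuracy
("reliable"), accuracy falls off sharply between 0.15 and 0.25
("degraded"), and above 0.25 no cell type retains good accuracy
("unreliable"). These are reported as guidance, never as hard gates.

Per-sample medians of the same relative residuals feed an outlier flag: a
sample is flagged when its residual exceeds $Q_3 + 1.5\,\mathrm{IQR}$ of
the per-sample residual vector. The definition of an outlier is a
convention; this one deliberately reuses the same Tukey fence the
simulator uses to construct outliers, so flagged-versus-injected agreement
is interpretable.

## Scoring and experiments

Because simulation noise makes some injected csDEGs genuinely undetectable
even from the uncontaminated per-sample profiles, scoring against the raw
injection mask would punish detectors for information that is not there.
The **gold standard** is instead re-derived from the known profiles: per
cell type, a two-sided Wilcoxon rank-sum test per gene between groups,
BH across genes, keep FDR $\le 0.05$. The rank-sum test is used because it
is assumption-light and its membership near the threshold is stable across
the simulation regimes.

**Top-list accuracy** compares like with like: with $k$ the gold-standard
size for a cell type, it is the fraction of the detector's top-$k$ genes
(ranked by p, ties by $|$effect$|$ descending, then gene id — detector
p-values, not FDR, because permutation FDRs are heavily tied) that are in
the gold standard. Precision and recall at FDR $\le q$ are also reported;
metrics that would divide by zero (empty gold standard, zero detections)
are explicit `NA`s, never silent zeros.

Experiment runners sweep one factor and score everything else identically:
`run_cv_experiment()` (heterogeneity grid, default levels 0.1, 0.5, 1,
1.5, 2, 2.5, all cell types or one target), `run_proportion_experiment()`
(target cell type's mean proportion varied, remaining mass redistributed
proportionally with proportion CVs preserved), and
`run_outlier_experiment()` (outlier counts; counts are split half case /
half control with the odd one to case — the single-dataset convention of
1 case + 5 control is available directly through `sim_config`). The gold
standard in the outlier experiment is always computed from the non-outlier
samples, so scores isolate the contamination effect. Per-level aggregation
uses the median over replicates.

## Numerical and design choices

* Quartiles everywhere are type-7 (linear interpolation).
* Sub-seeds are derived from the master seed by a fixed affine map modulo
  $2^{31}-1$, keeping every derived seed a valid 32-bit integer.
* The rank-deficiency check on designs names the collinear cell types in
  its error, since the usual cause (a cell type expressible as a
  combination of others, or constant proportions) is fixable by the user.
* `rank_genes()` tie-breaks are total (p, then $|$effect$|$, then gene
  id), so rankings are reproducible across platforms.
* Problem sizes in the shipped tests and benchmark — 1000–2000 genes,
  groups of 50–100 samples, 100–1000 permutations, 3 replicates per grid
  point — were chosen as the smallest sizes at which the benchmark's
  contrasts (calibration bands, monotone degradation, robust-vs-OLS
  ordering) are stable across seeds; the flagship configuration in
  `run_rare_cell_benchmark()` uses the full 2 × 100 samples design.

## Known limitations

* Proportions are treated as known and error-free; noisy composition
  estimates would add a second error source the benchmark does not model.
* The closed-form detectors inherit mild anticonservatism from
  heteroskedasticity (see above); their p-values should be read
  accordingly at scale.
* NNLS standard errors are approximations; use the permutation detector
  for inference on the non-negative core.
* The residual bands were calibrated on blood-like mixtures of 4–6 cell
  types; tissues with very few expressed genes or extreme compositions
  may not follow them.
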