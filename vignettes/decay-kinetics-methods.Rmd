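---
title: "Methods: decay kinetics, regulation coefficients and half-life determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay kinetics, regulation coefficients and half-life determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratechase)
```

# The measurement model

A rifampicin chase blocks transcription initiation at *t* = 0; afterwards
each transcript is lost by first-order degradation (dilution by growth is
negligible over the chase window when generation times are tens of times
longer than half-lives, which `dilution_negligible()` checks with a default
ratio of 10 between `k` and `µ/60`). The measured intensity of gene *g* on a
membrane at time *t* is then

$$\ln I_g(t) = \ln [mRNA]_{0,g} - k_g t + \ln \gamma_b + \varepsilon,$$

where $\gamma_b$ is a batch gain (exposure/labelling of one membrane
series) and $\varepsilon$ the measurement noise on the log scale. Two
consequences structure the pipeline:

- **Normalization** (`normalize_to_reference()`) divides every membrane in
  a batch by the scalar mean of that batch's pre-arrest (*t* = 0) reference
  membrane. This cancels $\gamma_b$ exactly while leaving every within-gene
  slope untouched. Since the decay fit pools all batches into a single
  regression with one intercept, removing between-batch gain differences
  also shrinks the residual variance and hence σ_k; the slope itself is
  unchanged by normalization under a balanced design (the batch term is
  orthogonal to time), which the tests verify exactly.
- **Fitting** (`fit_decay()`) is ordinary least squares of ln intensity on
  time, pooling all replicate membranes into one regression per gene
  rather than averaging replicate fits: pooling uses every point's leverage
  and gives a single, well-defined standard error for the slope.

σ_k is defined here as the relative standard error of the pooled slope in
percent, $100 \cdot SE(\hat\beta)/|\hat\beta|$. Classification follows the
field's convention: reliable when σ_k ≤ 30 %, extremely stable when the
slope is flat/rising or σ_k ≥ 70 % (the chase window is too short to
measure such transcripts), not determined otherwise. The thresholds are
arguments with these defaults. The *t* = 0 point is part of the measured
series and is included in the regression. Non-positive intensities are
dropped per point (never imputed) and a gene must keep at least three
distinct time points or its fit is refused.

# Regulation coefficients

At steady state, synthesis balances loss:
$V_T = (\mu/60 + k)\,[mRNA]$ with µ in h⁻¹ converted to min⁻¹ wherever it
meets a decay constant (half-lives are in minutes throughout, growth rates
in h⁻¹). Between two conditions, assuming $V_T$ and $k$ vary
independently,

$$\rho_D = -\frac{\Delta \ln k}{\Delta \ln [mRNA]}, \qquad
  \rho_T = 1 - \rho_D,$$

which partitions the mRNA-level change between decay and synthesis. Modes:
ρ_D = 1 pure degradational control, ρ_D = 0 pure transcriptional control,
0 < ρ_D < 1 shared, ρ_D > 1 and ρ_D < 0 antagonistic control dominated by
degradation and transcription respectively. The exact modes are called
within a tolerance band (default 0.05) since a fitted ρ_D never equals an
integer exactly; the headline bins use the closed/open edges ρ_D ≤ 0,
0 < ρ_D < 1, ρ_D ≥ 1 verbatim.

Two numerical guards matter:

- Genes whose concentration barely changes make ρ_D a near-0/0 ratio. An
  `epsilon` guard (default 0.05 on |Δln[mRNA]|, i.e. ~5 % concentration
  change) reports such genes as *undetermined* instead of forcing them
  into a bin.
- The concentrations entering ρ_D must share a scale across conditions.
  Per-batch reference normalization rescales each condition by its own
  average transcript level, which would add one constant to every
  Δln[mRNA] and bias every ρ_D. `initial_levels()` therefore averages the
  *raw* *t* = 0 membranes, which are comparable across conditions because
  the assay hybridizes the same amount of total RNA per membrane.

Transcription rates are derived from the steady-state balance for
diagnostics only; they are never measured. The statistic is strictly
pairwise; no attempt is made to regress ρ across more than two conditions.

# Sequence features and the covariance model

- **CAI**: relative adaptiveness $w = f_{codon} / \max f_{synonym}$
  computed from a highly expressed reference set (canonically ribosomal
  protein CDS), pseudo-count 0.5 for codons unobserved in the reference;
  gene CAI is the geometric mean of $w$ over codons, excluding stops and
  the single-codon families Met and Trp whose weight is 1 by construction.
- **tAI**: per-codon absolute adaptiveness is the copy-number-weighted sum
  over recognizing tRNAs, with the Watson–Crick decoder at full efficiency
  and one wobble decoder discounted by the published selective constraints
  (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68); weights are normalized to
  their maximum and combined by geometric mean. Codons no supplied tRNA
  reads are excluded from the product with a warning rather than imputed.
- **Upstream windows** are −100..+1 relative to the first base of the
  start codon (101 nt), reverse-complemented on the minus strand;
  truncated with a warning at sequence ends. AGGAG motifs are counted
  allowing overlaps, on the given strand only. Folding free energies are
  accepted as a two-column table from a standard folding tool run at the
  culture temperature; the model uses |ΔG|. No internal structure
  prediction is attempted.

The determinants model is an ANCOVA of ln t½. The response transform and
predictor scaling are design choices (the tables such models are compared
against do not state theirs): quantitative predictors are z-scored so
coefficients are directly comparable across features of different units,
and the log response makes the growth-rate effects additive. Qualitative
terms (growth-rate level, functional category, motif class binned 0/1/2+)
enter as factor contrasts. Model search is bidirectional stepwise AIC from
the full candidate model with the intercept-only model as lower scope;
`step()`'s preference order means an equal-AIC removal is taken, i.e. ties
break toward the smaller model. Constant and aliased (rank-deficient)
candidates are dropped before the search and reported. Because selection
is AIC-based, a 1-df null term survives with probability
P(χ²₁ > 2) ≈ 0.157 — the false-retention rate the null-simulation tests
pin down.

`growth_rate_only_r2()` refits the same candidate set minus the
growth-rate factor within each growth-rate level; comparing those R²
values with the pooled model's quantifies how dominant the growth-rate
term is.

# Clustering

Half-life profiles across growth rates are clustered with Ward's
minimum-variance criterion on Euclidean distances (`hclust` method
`ward.D2`, the Ward criterion for unsquared Euclidean input). Distances
are computed on raw half-lives in minutes, since all coordinates share
units; a log-scale option exists for when fold-changes matter more than
minutes. The flat cut is by requested cluster count — the choice of count
is graphical/judgmental and deliberately not automated. Labels are
deterministic in input order, so permutations change labels only up to
relabeling. Cluster summaries are per-condition member means with
two-sided t-intervals (`confidence = 0.05` gives the 95 % interval);
singleton clusters report an undefined interval rather than a zero-width
one.

# What the synthetic data emulate — and what they do not

`generate_chase()` reproduces the design features that drive the
estimators: exponential per-gene decay after arrest; steady-state initial
abundances consistent with $V_T = (\mu/60 + k)[mRNA]_0$; a default grid of
0, 1, 2, 4, 6, 10, 15, 20 min spanning a 20-minute chase (the real
sampling times within the window are not published, so the grid is
configurable); 2 biological × 2 technical replicate series, each a batch
with its own log-normal gain (SD 0.15); additive Gaussian noise on ln
intensity (the log-linear fitting model's conjugate noise; no noise model
is published), default SD 0.1; and a subpopulation of extremely stable
transcripts simulated with k *exactly* 0 — an unambiguous truth class for
the σ_k filter, rather than merely-small k whose classification would be
noise-dependent. The decay-rate distribution is log-normal with the median
half-life calibrated to 5.8 min (the fast-growth condition) and ln-k SD
0.5, and 5 % of genes extremely stable by default.

`generate_paired_conditions()` inverts the ρ_D algebra exactly: given a
concentration change and a target ρ_D, condition-b truth is
$k_b = k_a e^{-\rho_D \Delta\ln m}$, $m_b = m_a e^{\Delta\ln m}$, with
|Δln m| drawn in [0.5, 1.5] so the epsilon guard never bites by
construction. `generate_feature_table()` generates features with known
effect sizes on ln t½: the concentration and length coefficients use the
magnitudes such determinant analyses report (−0.065, −0.059), |ΔG| and CAI
use ±0.06 — a deliberately detectable ≈4-SE effect at 486 × 3
observations, the standard design point for a recovery simulation, since
marginal ~2-SE effects cannot be retained by any selector at a 90 % rate —
growth-rate level effects (0.763, 0.189, −0.952) dominate everything else,
and residual SD 0.55 puts the full-model R² near 0.6. GC, tAI and
position are generated as pure noise so selection has something to
reject.

None of the generators simulate spot-level image artifacts, probe
cross-hybridization, membrane spatial effects, or library/batch effects
correlated with time — so passing tests demonstrate correctness of the
estimators under the stated model, not robustness to structured artifacts
real membranes can carry. The real dataset's absolute numbers (mean
half-lives per growth rate, the exact Table-style percentages and
coefficients) depend on raw-image processing that is out of scope here;
the tests therefore check parameter *recovery* against synthetic truth,
not reproduction of published dataset-level values.

# Problem sizes and determinism

The test suite and the acceptance script use 2000-gene chases for
recovery statistics, 500-gene pairs for regulation mixes, 486 × 3
feature tables with 50 selection replicates, and 486-profile clusterings —
sizes at which the Monte-Carlo statistics asserted (median errors,
retention rates) are stable to well inside the asserted margins. All
randomness flows from explicit integer seeds; a dataset, pipeline run or
acceptance report regenerated with the same seed is bit-identical.

# Known limitations

- σ_k is the SE of one pooled slope; if replicate series had strongly
  heterogeneous slopes (e.g. biological-condition drift between
  replicates), a hierarchical model would be more honest than pooling.
- The ρ_D/ρ_T decomposition assumes independent V_T and k and exact
  steady states on both sides; transient conditions violate it.
- CAI/tAI use the standard wobble and pseudo-count conventions; organisms
  with unusual decoding (e.g. heavy anticodon modification) need a custom
  penalty vector.
- Stepwise AIC is a greedy search; with strongly collinear candidate
  features the selected set is one of several near-equivalent models, and
  coefficients should be read qualitatively (sign and rank), not as
  causal effect sizes.
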