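# ratechase

Genome-wide mRNA decay kinetics and regulation analysis from
transcription-arrest (rifampicin-chase) time courses, for bacterial
transcriptomics.

When transcription initiation is blocked with rifampicin at *t* = 0, the
level of each transcript decays (to first order) exponentially, so its
log intensity is linear in time:

    ln[mRNA](t) = ln[mRNA]₀ − k·t,      t½ = ln 2 / k

`ratechase` estimates the per-gene degradation rate constant *k* (min⁻¹) by
pooled ordinary least squares across replicate membrane series, attaches a
reliability call from the relative standard error of the slope
(σ_k ≤ 30 % reliable; flat/rising slopes or σ_k ≥ 70 % extremely stable),
and then builds three downstream analyses on the fitted constants:

- **Regulation analysis.** At steady state `V_T = (µ/60 + k)·[mRNA]`.
  Between two growth conditions the change in mRNA level is decomposed into
  a degradational coefficient `ρ_D = −Δln k / Δln[mRNA]` and its
  transcriptional complement `ρ_T = 1 − ρ_D`, and each gene is classified
  into the five regulation modes (pure degradation ρ_D = 1, pure
  transcription ρ_D = 0, shared 0 < ρ_D < 1, antagonistic ρ_D > 1 or
  ρ_D < 0) and the three headline bins (ρ_D ≤ 0 mainly transcriptional,
  0 < ρ_D < 1 shared, ρ_D ≥ 1 mainly degradational).
- **Half-life determinants.** Per-gene sequence features — CAI (geometric
  mean of relative codon adaptiveness against a highly expressed reference
  set), tAI (wobble-discounted tRNA copy-number weights), GC content,
  upstream |ΔG| (read from standard folding-tool output), overlapping
  AGGAG motif counts in the −100..+1 region — feed an ANCOVA of
  ln t½ with z-scored quantitative terms and factor terms (growth rate,
  functional category, motif class), selected by bidirectional stepwise
  AIC.
- **Profile clustering.** Ward minimum-variance hierarchical clustering of
  per-gene half-life profiles across growth rates, with flat cuts,
  per-cluster mean profiles with t-intervals, and newick export of the
  merge tree.

A first-class synthetic-data module (`generate_chase()`,
`generate_paired_conditions()`, `generate_feature_table()`) simulates the
whole design — exponential decay after arrest, steady-state initial
abundances, 2 biological × 2 technical replicate membranes, multiplicative
log-normal noise, a subpopulation of extremely stable transcripts — with
known per-gene ground truth, so every stage is testable end to end.

## Worked example

```r
library(ratechase)

# simulate a chase at fast growth and fit per-gene decay
d    <- generate_chase(synth_params(n_genes = 300, seed = 1))
fits <- fit_decay(normalize_to_reference(d$intensities))
dplyr::count(fits, status)
#> # A tibble: 3 × 2
#>   status               n
#>   <chr>            <int>
#> 1 extremely_stable    13
#> 2 not_determined       2
#> 3 reliable           285

summarize_halflives(fits)$stats
#> # A tibble: 1 × 4
#>       n  mean    se median
#>   <int> <dbl> <dbl>  <dbl>
#> 1   285  6.35 0.193   5.86
```

285 of 300 genes give reliable fits; the recovered median half-life
(5.86 min) matches the generator's 5.8 min calibration, and the mean ±
SE (6.35 ± 0.19 min) is the summary the fit table reports for a fast-growth
condition. The extremely stable genes are the simulated k = 0
subpopulation plus near-flat fits the σ_k ≥ 70 % rule catches.

Doubling times follow the same first-order arithmetic as half-lives:

```r
doubling_time(c(0.11, 0.51, 0.80, 0.38))
#> [1] 6.3013380 1.3591121 0.8664340 1.8240715   # hours
```

Pairwise regulation between two conditions:

```r
pair <- generate_paired_conditions(
  synth_params(n_genes = 500, mu = 0.80, seed = 2),
  synth_params(n_genes = 500, mu = 0.51, seed = 3),
  rho_d_targets = runif(500, -2, 0)  # mainly transcriptional by design
)
# fit each condition, join reliable k with pre-arrest levels, then:
# regulation_coefficients(state_a, state_b) |> summarize_regulation()
```

`run_pipeline()` drives the whole chain (simulate/load → normalize → fit →
regulate → cluster → report) from a YAML config and writes provenance-
stamped TSV artifacts. `autoplot()` / `plot_*()` methods cover each result
type; `tidy()` and `glance()` expose the covariance-model fit.

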