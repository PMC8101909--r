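# haplopop

Population-genetic analysis of aligned mitochondrial DNA sequences sampled
across a hierarchy of collection sites, areas and disjunct ranges — the
classic workflow used to decide whether an insect outbreak (or any sudden
demographic surge) arose from structured native populations or from an
introduced lineage. The package is aimed at molecular ecologists who have
per-marker FASTA alignments and a sample-to-site table, and who want the
full chain from haplotypes to expansion dating in one scriptable, seeded
run, with no external software.

## What it computes

* **Haplotypes and sites** — exact-match haplotype collapsing (missing
  data never merges sequences), per-column classification into invariant,
  singleton and parsimony-informative sites, and NUMT screening by
  translating the coding sub-region (invertebrate mitochondrial code,
  declared frame — never auto-detected).
* **Distances** — Kimura two-parameter distances
  `d = -1/2 ln[(1-2P-Q)√(1-2Q)]` with transition proportion `P` and
  transversion proportion `Q`, pairwise deletion; raw difference counts.
* **Diversity** — Nei's gene diversity `H = n/(n-1)(1-Σp_i²)` with its
  sampling variance, nucleotide diversity
  `π = n/(n-1) Σ_{i<j} 2 p_i p_j d_ij`, and mean pairwise differences.
* **Structure** — distance-based hierarchical AMOVA (Excoffier's
  two-level decomposition) with Φ_CT, Φ_SC, Φ_ST and permutation tests;
  pairwise Φ_ST; the Raymond–Rousset exact test of population
  differentiation (Markov chain over fixed-margin contingency tables).
* **Networks** — statistical-parsimony (TCS-style) haplotype networks:
  a 95% probability-of-parsimony connection limit, stepwise agglomeration
  with inferred intermediate nodes, and rule-based loop resolution
  (frequency, then interior-vs-tip, then shared geography), exported as
  GraphML/TSV.
* **Demography** — Tajima's `D = (k̂ - S/a₁)/√(e₁S + e₂S(S-1))` with a
  fixed-S coalescent p-value; Fu's `Fs = ln(S′/(1-S′))` with
  `S′ = Pr(K ≥ k_obs | θ = k̂)` under the Ewens sampling distribution
  (log-space Stirling numbers); the sudden-expansion mismatch model
  `F_i(τ, θ₀, θ₁)` fitted by bounded least squares with a parametric
  bootstrap for SSD, Harpending's raggedness and a τ confidence interval;
  and expansion dating `t = τ/(2·rate·L)`.
* **Simulation** — a coalescent generator in mutational-time units
  (constant size, sudden expansion, two-range split with no migration)
  whose pairwise coalescence-age density matches the fitted mismatch
  model exactly, plus a deterministic 130-sample / 1697-bp / 32-haplotype
  two-range dataset for exercising every stage without downloads.

## Worked example

```r
library(haplopop)

fx  <- make_paper_fixture(seed = 1)          # built-in two-range dataset
tab <- collapse_haplotypes(fx$alignment, fx$popmap, labels = fx$truth$labels)
tab
#> Haplotype table: 32 haplotypes, 130 samples, 23 site(s)

summarize_populations(fx$alignment, fx$popmap, grouping = "area")
#>      range            area  n k    H  sd_H pi_pct k_hat
#> 1 Euganean  Euganean_North 20 7 0.64 0.118  0.046  0.78
#> 2 Euganean Euganean_Center 20 7 0.73 0.092  0.072  1.22
#> 3 Euganean  Euganean_South 17 4 0.50 0.135  0.038  0.65
#> 4   Berici    Berici_North 25 9 0.80 0.063  0.085  1.45
#> 5   Berici   Berici_Center 16 8 0.91 0.040  0.100  1.69
#> 6   Berici    Berici_South 20 3 0.28 0.123  0.022  0.37
#> 7  Lessini         Lessini 12 3 0.71 0.069  0.087  1.47
```

`H` is the probability that two sequences drawn from the area carry
different haplotypes; `pi_pct` the average K2P distance between two drawn
sequences, in percent; `k_hat` the mean pairwise difference count that
feeds the mismatch analysis. A demographic scan of one range:

```r
eug <- fx$popmap$sample_id[fx$popmap$range == "Euganean"]
sub <- as_alignment(unclass(fx$alignment)[eug, ], "Euganean")
nt  <- neutrality_tests(sub, n_sim = 1000, seed = 1)
#> D = -2.13 (p = 0.004), Fs = -15.61 (p = 0.001)

mm  <- mismatch_observed(pairwise_distances(sub, "raw"))
fit <- fit_sudden_expansion(mm, n = nrow(sub), B = 1000, seed = 2)
fit
#> Sudden-expansion fit: tau = 1.016 (0.226-1.636), theta0 = 0.000252,
#>   theta1 = 3.28e+04
#> SSD = 0.001176 (p = 0.479), raggedness = 0.06344 (p = 0.475), B = 1000

expansion_time(fit$tau, 1697, 2.3e-8, fit$tau_ci)$t_ka
#> 13.0   # thousand years before present (CI 2.9-21.0)
```

The strongly negative `D` and `Fs` (haplotype excess over pairwise
diversity), the smooth mismatch fit that the bootstrap does not reject
(`p_SSD`, `p_r` ≈ 0.5), and a late-glacial expansion age are exactly the
signature of a native population that expanded from a small refugium —
the scenario the synthetic dataset encodes.

The whole chain — concatenation, NUMT screen, diversity, exact test,
AMOVA, network, demography — runs end-to-end from a YAML config with
`run_pipeline()`; see `vignette` sources under `vignettes/` and
`inst/scripts/run_pipeline.R` for a shell entry point.

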