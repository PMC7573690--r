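# homomer

Statistical analysis of protein homo-oligomerization degree: how often
do proteins assemble into complexes of k identical subunits, and why
does that frequency fall off the way it does?

The package is for computational biologists working with proteome
annotation tables (UniProt-style subunit-structure text or explicit
subunit numbers) and protein-protein interaction edge lists
(STRING-style TSV). It provides:

- **Frequency distributions** `f_s(k) = N_k / N_T` over subunit number
  k — whole proteome, even/odd parity subsets (with either an
  all-known or a parity-renormalized denominator), GO-category and
  pathway strata, abundance-weighted variants, and cross-organism
  averages.
- **Power-law fits**, two ways. Small frequency tables get ordinary
  least squares on `(log k, log f)` with a slope t-test
  (`loglog_ols_fit()`). Degree data get the discrete
  maximum-likelihood fit `P(k) ∝ k^-γ / ζ(γ, k_min)` with a
  KS-minimizing scan for the lower cutoff `k_min` and a semiparametric
  bootstrap goodness-of-fit p in which every replicate is refitted
  from scratch (`fit_degree_powerlaw()`); `p > 0.1` means the power
  law cannot be rejected.
- **The resource-precision model.** Synthesis cost grows linearly,
  `E(k) = 4.5 · L · k` ATP; a k-subunit complex with binary binding
  sites has `2^k` arrangements, so reaction precision scales as
  `2^-k`; the trade-off predicts `f_s(k) ∝ k / 2^k`
  (`fit_resource_model()`), with the information-capacity statistic
  `c(k) = f_s(k) · k` (`capacity()`), the cyclic-assembly necklace
  count `(1/k) Σ φ(d) 2^(k/d)` (`necklace_count()`), and the Hill
  response `H = s^n / (s^n + Kd)` (`hill_response()`).
- **Network degree statistics**: `<d> = 2E/N`, per-protein connection
  probability `d/2E`, degree distribution, and mean degree per
  oligomer class with a correlation test against subunit number.
- **A seeded synthetic-data module** (`generate_proteome()`,
  `generate_degree_sequence()`, `realize_edges()`) generating data
  with the structure the analysis assumes, so the entire pipeline is
  testable offline.

## Worked example

Simulate a fully annotated proteome, compute the even-k distribution
renormalized over even states, and fit the model:

```r
library(homomer)
rec <- generate_proteome(proteome_sim_params(50000, known_fraction = 1, seed = 1))
d   <- oligomer_frequency(rec, parity = "even", denominator = "parity-subset")
d
#> Homo-oligomer distribution 'synthetic' (parity=even, denominator=parity-subset, weighting=count)
#>   total weight in denominator: 28163
#>                2         4         6        8       10      12
#> count 15879.0000 7897.0000 3035.0000 934.0000 329.0000 89.0000
#> freq      0.5638    0.2804    0.1078   0.0332   0.0117  0.0032

fit_resource_model(d, mode = "scaled")
#> Resource-precision model fit: f_s(k) = A * k / 2^k
#>   support: k = {2, 4, 6, 8}   mode: scaled
#>   scale A = 1.127   R-squared = 0.9999
```

The distribution falls as `k/2^k` (frequencies 0.56, 0.28, 0.11, 0.03
at k = 2, 4, 6, 8) and the one-parameter fit explains it almost
exactly. On the exact normalized model the capacity statistic makes
its diagnostic prediction `c(2) = c(4)`:

```r
capacity(model_frequency(c(2, 4, 6, 8)))
#>   k        f_s  capacity
#> 1 2 0.57142857 1.1428571
#> 2 4 0.28571429 1.1428571
#> 3 6 0.10714286 0.6428571
#> 4 8 0.03571429 0.2857143
```

Degree data: simulate a 10,000-node degree sequence with a planted
power-law tail (γ = 2.5 above k_min = 5) and recover it, bootstrap
included:

```r
deg <- generate_degree_sequence(network_sim_params(10000, gamma = 2.5, k_min = 5, seed = 1))
fit_degree_powerlaw(deg[deg > 0], n_boot = 200, seed = 2)
#> Discrete power-law fit (MLE + KS cutoff scan)
#>   P(k) ~ k^-2.513 for k >= 5   (n_tail = 6964 of 9821)
#>   KS distance D = 0.005015   bootstrap p = 0.645 (n_boot = 200)
```

The exponent and cutoff are recovered (2.513 vs 2.5, cutoff 5) and the
non-rejecting p = 0.645 says the tail is consistent with a power law.

End-to-end runs with report bundles (JSON + tidy TSV + reproducibility
manifest) are available as `run_proteome_analysis()` /
`run_ppi_analysis()`, or from a shell via the thin CLI
`inst/cli/homomer-cli.R` (commands `simulate-proteome`,
`simulate-network`, `freq`, `fit-powerlaw`, `fit-model`, `ppi`,
`run-all`).

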