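# bcx — biocultural complexity from species-by-culture count tables

`bcx` is for ethnobiologists and quantitative ecologists who have a table
of interaction counts between biological taxa and cultural groups — use
reports of plants per ethnic group, mushroom collection records per
village — and want to know how *structured* the ensemble is: do the groups
lean on different subsets of the biota, or do they all draw on the same
pool?

Additive or correlative diversity summaries cannot answer this, because
they ignore the connections between the two axes.  `bcx` measures the
structure with the mutual information between taxa S and groups C
(base-2, in bits),

    I(S;C) = H_C − H_{C|S} = H_S − H_{S|C},

and reports its exponential, the **biocultural complexity**
`BC = 2^I(S;C)`: the effective number of biocultural units, from 1 (one
homogeneous unit) to c (every group with a private taxon set).  Around
this core the package computes:

* **taxon specificity** `S_i = H(C) − H(C|S_i)` — the information a taxon
  carries about who uses it (0 = uniform use, log2(c) = private);
* **group specialization** `δ_j = Σ_i f_{i|j} S_i` — the weighted mean
  specificity of a group's taxa; `I = Σ_i f_i. S_i = Σ_j f_.j δ_j` exactly;
* per-group Shannon diversity and relative (normalized) indices;
* **bootstrap** bias correction, standard errors and basic
  (reverse-percentile) confidence intervals for every index, from one
  shared stream of within-group multinomial resamples;
* a **Monte Carlo chi-square test** of taxon-by-group association with
  both margins fixed;
* a **simulator** with a tunable stratification parameter and a
  bias-correction calibration experiment.

## Worked example

The package ships a small demonstration table — five taxa, four cultural
groups of equal representation (weights coded 1) — as
`artificial_ensemble()` and as `inst/extdata/artificial_use_counts.csv`.

```r
library(bcx)
fit <- biocultural(artificial_ensemble(), b = 1000, seed = 42)
fit
#> Biocultural complexity model: 5 taxa x 4 cultural groups
#>   Mutual information I(S;C): 0.936 bits (max 2)
#>   Biocultural complexity:    1.91 effective units (of 4 groups)
#>   Bias-corrected complexity: 1.9  (95% CI 1.8-1.98, b = 1000)
```

The ensemble behaves like 1.9 fully distinct culture–biota units out of a
possible 4: clearly structured, far from fully stratified.  `summary(fit)`
prints the full per-taxon and per-group tables (raw, bias-corrected and
standard-error columns).  Taxon `sp1`, private to one group, hits the
specificity ceiling log2(4) = 2 bits; `sp2`, used by every group, sits
near 0.  The association test agrees that the structure is real:

```r
bc_chisq_test(artificial_ensemble(), B = 1999, seed = 42)
#> 	Pearson's Chi-squared test with simulated p-value (both margins fixed,
#> 	based on 1999 replicates)
#> X-squared = 547.36, B = 1999, p-value = 5e-04
```

Other entry points: `read_ensemble()`/`write_ensemble()` for CSV/TSV I/O,
`bc_bootstrap()` for a single statistic, `simulate_ensemble()` and
`recovery_experiment()` for calibration studies, and `coef()`,
`confint()`, `simulate()`, `residuals()`, `plot()` methods on the fitted
object.  A thin command-line wrapper lives at `exec/bcx`:

```sh
Rscript exec/bcx analyze inst/extdata/artificial_use_counts.csv --b 1000 --seed 42
Rscript exec/bcx test inst/extdata/artificial_use_counts.csv --B 2000
Rscript exec/bcx simulate --c 4 --s 8 --structure 0.7 --total 200 -o sim.csv
```

See `vignettes/biocultural-complexity.Rmd` for the model, the design
decisions (weights vs column totals, resampling scheme, clipping) and the
method's limitations.

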