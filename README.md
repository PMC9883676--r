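# xaemlite

Isoform-level quantification from multi-sample RNA-seq equivalence-class
counts under a **bilinear Poisson model**

    y_jn ~ Poisson(mu_jn),   mu_jn = sum_t x_jt * beta_tn,   sum_j x_jt = 1,

where `y_jn` is the read count of equivalence class `j` (the set of
transcripts a read maps to jointly) in sample `n`, `beta_tn` is the
abundance of transcript `t`, and `x_jt` is the proportion of transcript
`t`'s reads expected in class `j`.  Most quantifiers fix the design matrix
`X` from simplifying assumptions (uniform read distribution) and estimate
only `beta`; unknown biases then distort the estimates.  Here **both `X`
and `beta` are estimated jointly** by an alternating EM (AEM) algorithm: a
variational-Bayes digamma-weighted read allocation updates `beta` per
sample, and a pooled reallocation across samples re-estimates `X`,
empirically correcting biases that were never modelled explicitly.

The package is aimed at methods work on isoform quantification: it contains
everything needed to study the estimator end to end at desk scale — a toy
transcriptome and read simulator with an exact-substring mapper, the
empirical construction of the starting `X` from transcript response
profiles (neighbor filtering at threshold `H`, transcription clusters,
binary occupancy patterns, column normalization), paralog collapsing by
SVD + k-means, the AEM estimator, accuracy metrics (absolute proportion
error `|E - T| / (T + 1)`), and a differential-expression rediscovery-rate
analysis with CPM/log/median normalization.  Salmon-style `eq_classes.txt`
files and a simple TSV dialect are read natively.

## Worked example

The five-transcript example bundled as `fig_trps()` walks the whole
construction.  Transcript `tx5` receives only 2% of the source transcript's
reads and is removed by the 2.5% neighbor filter; the remaining profiles
collapse to three occupancy patterns over `tx1..tx4`:

```r
library(xaemlite)
ds <- build_design_set(trps = fig_trps(), H = 0.025, merge = FALSE)
ds$designs[[1]]
#> design matrix: 3 patterns x 4 transcripts
#>       tx1  tx2 tx3  tx4
#> 1101 0.02 0.12   0 0.15
#> 1110 0.85 0.88   1 0.00
#> 1001 0.13 0.00   0 0.85
```

Each column gives the fraction of that transcript's reads per pattern
(columns sum to 1); pattern `1101` means the class is shared by `tx1`,
`tx2` and `tx4`.

Quantification on simulated data — build a 3-isoform gene, generate counts
from a known truth, and fit:

```r
tr <- make_toy_transcriptome(1, 3, 200, 200, seed = 3)
X  <- build_design_set(tr, seed = 3)$designs[[1]]
beta_true <- matrix(runif(3 * 50, 500, 5000), 3,
                    dimnames = list(colnames(X), sprintf("s%02d", 1:50)))
Y   <- simulate_multisample_counts(X, beta_true, seed = 9)
fit <- aem_fit(Y, X, update_X = TRUE)
fit
#> AEM fit: 3 transcripts x 50 samples, 5 iterations (converged), beta0 = 2732.467
round(fit$counts[, 1:3], 1)      # estimated read counts per sample
#>         s01    s02    s03
#> g1t1 1715.6 1887.3 1552.2
#> g1t2 3324.1 4359.6 3854.0
#> g1t3 2854.3 4590.1 2671.7
recovery_report(fit$counts, beta_true)
#>   category n median_ape   pearson  spearman
#> 1      all 3  0.0739167 0.9865742 0.9847958
```

`fit$counts` is `beta - beta0`, the reads allocated to each transcript (the
prior pseudo-count `beta0` is the mean read count per transcript per
sample); the median absolute proportion error of 0.07 and correlation 0.99
show the truth is recovered up to Poisson noise and the mild shrinkage the
prior induces.  With `update_X = FALSE` the design matrix stays fixed — the
conventional estimator without empirical bias correction — which is the
right baseline when comparing against the full AEM on bias-distorted data
(`apply_bias()`).

A thin command-line wrapper is installed at
`system.file("cli", "xaemlite", package = "xaemlite")` with subcommands
`simulate`, `buildx`, `quantify`, `evaluate`, `de` and `run`.

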