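# fvtlda

Predicting lncRNA–disease associations from tripartite miRNA-centred
association networks.

Experimentally confirmed links between long non-coding RNAs (lncRNAs) and
diseases are scarce, while miRNA-centred evidence — miRNA–disease links and
miRNA–lncRNA interactions — is abundant. `fvtlda` scores every
(lncRNA, disease) pair by learning the relationship between

* **pair feature vectors** `FV(i,j) = PL(i) ⊗ PD(j)` — the elementwise
  product of the two endpoints' random-walk-with-restart profiles over the
  miRNA universe, where the lncRNA-side walk runs on a Gaussian
  interaction-profile (GIP) kernel network
  `KM(i,j) = exp(−γ_m ||IP_i − IP_j||²)` and the disease-side walk on a
  best-match-average functional similarity network built from MeSH-based
  disease semantic similarity; and
* **association probability targets** — the binary lncRNA–disease matrix
  smoothed by attenuated similarity-weighted voting,
  `OUT = rate·FOUT + (1−rate)·DOUT`, min–max normalized to [0, 1],

using either multiple linear regression (minimum-norm least squares) or a
small feed-forward neural network (10 tanh hidden units, linear output,
Levenberg–Marquardt training with validation-based early stopping).
Because the features never touch the lncRNA–disease matrix itself,
diseases without any known lncRNA (and vice versa) still get ranked.

The package ships the full evaluation machinery — leave-one-out and k-fold
cross-validation with masked-target refitting and rank-based ROC/AUC,
case-study candidate ranking with the contrast score
`exp(Σ 1/Rᵢ − Σ 1/i)` — plus a seeded synthetic tripartite generator with
planted block structure, so everything builds and tests without any
download. Audience: computational biologists doing network-based
association inference, and anyone who needs a self-contained,
tested reference implementation of this model family.

## Worked example

```r
library(fvtlda)

sim  <- simulate_tripartite(seed = 42)        # planted 4-group structure
data <- as_fvtlda_data(sim)
pars <- fvtlda_params(r1 = 0.3, r2 = 0.3)     # walk restart for small networks

fit <- fvtlda_fit(data, model = "mlr", params = pars)
fit
#> <fvtlda_fit> MLR scorer over 30 lncRNAs x 25 diseases (98 known associations, 40 miRNA features)

glance(cv_associations(fit, scheme = "loocv"))
#> # A tibble: 1 × 7
#>   scheme model     k repeats auc_mean auc_sd n_positives
#>   <chr>  <chr> <int>   <dbl>    <dbl>  <dbl>       <int>
#> 1 loocv  mlr      98       1    0.806     NA          98

case_study(fit, "disease-001", top = 5)
#> <fvtlda_case_study> disease-001
#> # A tibble: 5 × 4
#>   lncrna  score  rank verified
#>   <chr>   <dbl> <int> <lgl>
#> 1 lnc-025 0.514     1 FALSE
#> 2 lnc-009 0.501     2 FALSE
#> 3 lnc-029 0.434     3 FALSE
#> 4 lnc-017 0.277     4 FALSE
#> 5 lnc-016 0.201     5 FALSE
```

The leave-one-out AUC of 0.806 says that a held-out known association
outranks a random unknown pair 81% of the time; on the same data with the
known links shuffled the AUC falls to chance (≈ 0.5), so the ranking
reflects the planted structure, not leakage. `tidy()`/`glance()` work on
fitted models and cross-validation results, and `autoplot()` draws the ROC
curve or the score heat map.

The shipped case-study benchmark reproduces the published contrast scores
of three candidate rankers on gastric cancer, leukemia and lung cancer:

```r
benchmark_contrast_scores()
#> # A tibble: 9 × 4
#>   disease        method         m contrast_score
#>   <chr>          <chr>      <int>          <dbl>
#> 1 gastric cancer FVTLDA_ANN    10         0.838
#> 2 gastric cancer FVTLDA_MLR    10         0.717
#> 3 gastric cancer KATZLDA       10         0.844
#> 4 leukemia       FVTLDA_ANN     8         0.975
#> 5 leukemia       FVTLDA_MLR     8         0.945
#> 6 leukemia       KATZLDA        8         0.969
#> 7 lung cancer    FVTLDA_ANN     8         0.741
#> 8 lung cancer    FVTLDA_MLR     8         0.861
#> 9 lung cancer    KATZLDA        8         0.0998
```

A thin command-line front end wraps the same functions:

```sh
inst/cli/fvtlda simulate   --out data/ --seed 1
inst/cli/fvtlda evaluate   --dir data/ --scheme loocv --model mlr --params r1=0.3,r2=0.3
inst/cli/fvtlda case-study --dir data/ --disease disease-001 --top 10
```

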