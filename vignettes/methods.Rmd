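---
title: "Scoring lncRNA-disease associations from tripartite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lncRNA-disease associations from tripartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvtlda)
library(dplyr)
```

## The prediction problem

Experimentally confirmed lncRNA-disease associations are scarce, while
miRNA-centred evidence — miRNA-disease links and miRNA-lncRNA interactions —
is comparatively abundant. `fvtlda` scores every (lncRNA, disease) pair by
combining the two kinds of evidence:

* **Indirect evidence** enters through *features*. Every lncRNA and every
  disease is described by the stationary distribution of a random walk with
  restart over a miRNA similarity network, i.e. by how probability mass
  spreads from the miRNAs known to touch that entity to the rest of the
  miRNA universe. A pair's feature vector is the elementwise product of its
  two endpoint profiles: miRNA *k* contributes to the pair exactly to the
  extent it is network-close to both endpoints.
* **Direct evidence** enters through *targets*. The binary lncRNA-disease
  matrix is smoothed into graded association probabilities: a pair inherits
  attenuated votes from known associations of functionally similar lncRNAs
  and of semantically similar diseases.

A regression model — ordinary least squares or a small feed-forward neural
network — then learns the map from features to targets, and its predictions
on unknown pairs are the association scores. Because the features never use
the lncRNA-disease matrix itself, entities with *no* known association
still receive meaningful scores; that is the point of the construction.

## The similarity layers

**GIP kernel (miRNA side of the lncRNA walk).** Each miRNA's interaction
profile is its row of the miRNA-lncRNA incidence matrix, and

$$KM(i,j) = \exp(-\gamma_m \lVert IP_i - IP_j \rVert^2),\qquad
  \gamma_m = \gamma_m' \Big/ \sum_k \lVert IP_k \rVert^2,$$

with $\gamma_m' = 1$. `gip_kernel()` implements this form by default and
also offers `average = TRUE`, which divides by the *mean* squared profile
norm instead of the sum (the convention of the kernel's original
formulation). The two differ only in bandwidth scale; both are exposed
because the unaveraged bandwidth shrinks like $1/\text{(edge count)}$ and
therefore flattens the kernel on large networks.

**Disease semantic similarity.** A disease is located in the MeSH hierarchy
by its tree codes; its DAG is the set of codes plus all dot-prefix
ancestors. A node contributes 1 for the disease itself and $\Delta^k$ at
$k$ levels above it ($\Delta = 0.5$), and two diseases are compared by the
contribution mass of their shared nodes relative to their total semantic
values. Node identity is the tree-code string, so "sharing a node" means
sharing a code prefix; a disease filed at several positions contributes 1
once, with each position spawning its own ancestor lineage.

**Functional similarity.** miRNAs (and lncRNAs) are compared through their
associated disease sets by best-match averaging: every disease of one
entity is matched to the most similar disease of the other and the matches
from both directions are averaged over $p + q$. One code path serves both
instantiations — miRNAs against the miRNA-disease matrix, lncRNAs against
the lncRNA-disease matrix — each with the disease similarity restricted to
its own universe. An entity with an empty disease set scores 0 against
everything (1 on the diagonal): the neutral choice for a case the
construction never needs to rank.

## Walk features

The walk iterates $P_{s+1} = (1-r)\,N^{T} P_s + r P_0$, where $N$ is the
row-normalized similarity matrix and the seed column of an entity is
uniform over its known miRNA partners. Iteration stops when successive
iterates differ by less than $10^{-10}$ in max norm (cap 10000 iterations);
at convergence the iterate equals the closed form
$r\,(I - (1-r)N^T)^{-1}P_0$, which `rwr_closed_form()` provides as an
independent check. Column stochasticity is preserved exactly at every step,
and an entity with no miRNA partner keeps an all-zero profile rather than
raising an error — isolated nodes are scored, not rejected.

## Smoothed targets

With attenuation $k_1$ the lncRNA-side smoothing is

$$FOUT(i,j) = k_1 \sum_n LD(n,j)\,FL(i,n) \;+\; (1-k_1)\,[LD(i,j)=1],$$

and the disease side mirrors it with $k_2$ and the disease similarity. The
summation includes the self term, so a known pair with no other support
scores exactly 1. The set of diseases with nonzero similarity to a given
disease (its semantic clique) needs no explicit construction: zero
similarities contribute zero to the sum, so the full-matrix products
`FL %*% LD` and `LD %*% DS` are algebraically identical to the clique-wise
sums. The two sides are mixed as $rate \cdot FOUT + (1-rate) \cdot DOUT$
and min-max normalized over the whole matrix (not per row or column), which
also makes the targets invariant to any affine rescaling of the
combination.

## The two scorers

**Linear scorer.** `fit_mlr()` prepends an intercept and solves least
squares through the Moore-Penrose pseudo-inverse, returning the
minimum-norm solution. This survives exactly collinear feature columns
(which arise, e.g., when two miRNAs have identical partner sets) with
unchanged predictions.

**Neural scorer.** `fit_ann()` trains a single hidden layer of 10 units
with the activation $2/(1+e^{-2x})-1$ (algebraically $\tanh$) and one
linear output. Samples are split 3:1:1 into training, validation and test
portions; training minimizes the training MSE by a damped Gauss-Newton
(Levenberg-Marquardt) iteration, the standard optimizer for small
feed-forward regressors and far more effective than plain gradient descent
within a 100-epoch budget. Stopping: 100 epochs, training MSE below 0.001,
or 15 consecutive epochs without validation improvement — in every case the
best-validation weights are restored, and the test portion is only
reported, never used for stopping. Weights start uniform in
$[-0.5, 0.5]$ from a caller-supplied seed, making fits bit-reproducible.
Inputs are min-max mapped to $[-1, 1]$ per feature before training (stored
in the model, reapplied at prediction): walk profiles live on scales of
$10^{-2}$ and below, and this standard preprocessing keeps the
Gauss-Newton system well conditioned. The hidden-layer width is a free
choice; 10 units is the historical default of feed-forward toolchains of
this size and is exposed as `hidden`.

## Parameters

| parameter | meaning | default |
|---|---|---|
| `rate` | mix of lncRNA-side vs disease-side smoothing | 0.3 |
| `r1`, `r2` | restart probabilities of the two walks | 0.001 |
| `k1`, `k2` | smoothing attenuation factors | 0.008, 0.007 |
| `gamma_prime` | GIP bandwidth parameter | 1 |
| `delta` | semantic contribution decay | 0.5 |
| `rwr_tol`, `rwr_max_iter` | walk convergence controls | 1e-10, 10000 |

The defaults of `fvtlda_params()` are the values tuned on the method's
original benchmark (4704 miRNA-disease, 9086 miRNA-lncRNA and 407
lncRNA-disease associations). They are conditions of that benchmark, not
universal constants — see the next section for the one that does not
transfer to small networks.

## Cross-validation protocol

`cv_associations()` holds out known pairs (singly, or in k folds), masks
the held-out entries to zero, rebuilds the lncRNA functional similarity
and the smoothed targets *from the masked matrix*, refits the scorer on
all remaining pairs, and ranks each held-out pair among all unknown pairs.
The AUC is the concordance between held-out and unknown scores with ties
counted one half, which equals the area under the rank-swept ROC curve.
Masking matters: the held-out link otherwise raises its own smoothed
target and leaks the test label into training. The min-max normalization
is likewise recomputed on the masked matrix.

## The synthetic testbed

`simulate_tripartite()` plants a block structure: entities belong to
latent groups, edges appear with probability `p_in` within matched groups
and `p_out` otherwise, and disease tree codes share deep prefixes within a
group so the semantic layer is informative. Defaults: 40 miRNAs, 30
lncRNAs, 25 diseases, 4 groups, `p_in = 0.5`, `p_out = 0.03`, code lineage
depth 3 with 2 sibling branches per group — small enough that a full
leave-one-out run with the linear scorer takes about a second, large
enough that the planted signal dominates sampling noise. With
`p_in == p_out` the generator emits pure noise and the pipeline's AUC sits
at chance, which the test suite uses as a negative control alongside a
label-shuffled control (`shuffle_ld()`).

The generator emulates the *shape* of the real data — sparse binary
tripartite links, group-correlated ontology — but not its degree
heterogeneity, name noise, or literature-driven ascertainment bias, so
passing tests demonstrate correct mechanics and signal recovery, not
clinical performance.

**Restart probability on the testbed.** The benchmark-tuned
`r1 = r2 = 0.001` does not transfer to a 40-node network: at that restart
the walk essentially reaches the stationary distribution of the similarity
network, endpoint profiles collapse to near-identical columns, and the
pair features lose the seed information the predictor needs — under the
masked-target protocol the cross-validated AUC drops to chance. All
fixture-scale evaluations therefore use the field-standard restart of 0.3
for both walks (`fvtlda_params(r1 = 0.3, r2 = 0.3)`), chosen once from the
random-walk literature; every other parameter keeps its benchmark default.

## A worked run

```{r pipeline}
sim <- simulate_tripartite(seed = 42)
data <- as_fvtlda_data(sim)
pars <- fvtlda_params(r1 = 0.3, r2 = 0.3)

fit <- fvtlda_fit(data, model = "mlr", params = pars)
glance(fit)

cv <- cv_associations(fit, scheme = "loocv")
glance(cv)
```

```{r casestudy}
disease <- colnames(fit$ld)[1]
case_study(fit, disease, top = 5)
```

The shipped case-study benchmark (`case_study_benchmark()`) carries the
verified-candidate rank lists for gastric cancer, leukemia and lung cancer
under three scoring methods; `benchmark_contrast_scores()` turns each list
into the contrast score $\exp(\sum_i 1/R_i - \sum_i 1/i)$, which is 1 when
the verified candidates occupy the top ranks consecutively:

```{r contrast}
benchmark_contrast_scores()
```

## Numerical choices and degenerate inputs

* Ties in candidate ranking break by registry order (deterministic); the
  AUC itself uses the ties-half convention, so tie-breaking never moves it.
* All-zero similarity rows stay zero after row normalization (warning);
  all-zero seed columns yield all-zero walk profiles rather than errors.
* A constant combined smoothing matrix (e.g. an empty lncRNA-disease
  matrix) yields all-zero targets with a warning instead of 0/0.
* Unknown entity names in an association table abort by default;
  `on_missing = "drop"` downgrades them to a counted warning for messy
  curation dumps.
* Name canonicalization is case-fold + trim + collapse of internal
  whitespace runs — deterministic and documented, since upstream databases
  disagree on casing and spacing. No attempt is made to merge miRNA arm
  variants (-3p/-5p); that normalization is upstream curation.

## Known limitations

* The disease similarity treats a disease's multiple tree positions as
  separate shared-or-not code strings; the alternative reading (collapsing
  all positions into one node when both diseases contain any of them)
  would score multi-position diseases slightly higher.
* The internal test portion of the neural scorer's 3:1:1 split is reported
  but unused; its role in the original training recipe is unspecified.
* Scores from the linear scorer are unbounded (they are used only for
  ranking); they are not calibrated probabilities.
* Cross-validation refits the full scorer per fold; leave-one-out with the
  neural scorer on datasets much beyond a few hundred known pairs is
  better run as repeated k-fold.
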