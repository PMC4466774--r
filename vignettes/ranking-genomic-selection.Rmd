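---
title: "Ranking-based genomic selection: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking-based genomic selection: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrank)
```

## The problem

Genomic selection predicts the genetic merit of breeding candidates from
genome-wide marker genotypes. A reference population of $n$ individuals is
genotyped at $p$ markers (rows $x_i \in \mathbb{R}^p$ of a matrix $X$, codes
0/1/2 for allele counts) and phenotyped for a quantitative trait
$y \in \mathbb{R}^n$; a model fitted on these data then scores new
candidates, of which only the top $k$ are advanced to field testing. Two
features make this setting distinctive. First, $n \ll p$: a few hundred
phenotyped individuals against thousands of markers, which forces
regularized or dual (kernel) formulations. Second, and central to this
package, the breeder's question is not "what will each candidate's trait
value be?" but "which $k$ candidates are best?" — a *ranking* question.
`gsrank` treats it as one: it provides ranking-specific evaluation measures,
learners that optimize ranking surrogates directly, regression baselines for
comparison, a cross-validation benchmarking protocol, and a synthetic
genotype/phenotype simulator so every component is testable without external
data.

## Evaluation measures

**MSE and Pearson correlation** are the traditional measures. Correlation
already ignores scale and location ($r = 1$ for any prediction
$\hat{y} = a y + b$, $a > 0$), but it still demands collinearity, which is
stricter than correct ordering: `pearson(c(3.5, 2.8, 1.2), c(10.3, 3.7, 0.1))`
is `r round(pearson(c(3.5, 2.8, 1.2), c(10.3, 3.7, 0.1)), 2)` even though
the prediction orders the three individuals perfectly.

**Pair-based global measures.** The preference set
$P(y) = \{(i, j) : y_i > y_j\}$ collects all strict preferences. Against
predicted scores, each preference pair is concordant, discordant or tied;
pairwise accuracy is $|C|/|P|$ and Kendall's $\tau$ is $(|C| - |D|)/|P|$.
With no score ties $\tau = 2\,\mathrm{pa} - 1$ exactly. Two conventions are
deliberate: the denominator is always $|P(y)|$ (strict preferences of the
reference only), so on references with ties this is the $\tau_a$-style
statistic and *not* the $\tau_b$ tie correction that
`cor(method = "kendall")` applies — documented to avoid silent disagreement
with standard routines; and a constant reference is an error rather than a
zero, because an empty preference set carries no signal to score against.

**Top-$k$ measures.** DCG at position $k$ is
$\sum_{i=1}^{k} g(y_{\pi_i})\, d(i)$ for the score-induced ranking $\pi$,
with gain $g$ and discount $d$; NDCG divides by the DCG of the ideal
(trait-sorted) ranking and lies in $[0, 1]$ for nonnegative traits; Mean
NDCG@$K$ averages NDCG@$k$ over $k = 1..K$. Defaults are the linear gain
$g(y) = y$ (trait values are unbounded, unlike the small relevance grades
that motivate the exponential gain in document retrieval) and the
logarithmic discount $d(i) = 1/\log_2(i + 1)$, with $k \in \{1, 5, 10\}$
the positions of practical interest when few candidates are advanced;
exponential gain and the unit discount are exposed as options. Traits must
be nonnegative for NDCG: `shift_nonnegative()` subtracts the minimum over
the whole dataset. The shift leaks a single constant across CV splits, to
which every implemented measure except raw (unnormalized) DCG is
invariant, so it is applied per dataset rather than per split. Numerical
conventions: score ties in `induced_permutation()` break by ascending
index (the choice is arbitrary but must be deterministic for testability),
and an all-zero reference within the top $k$ makes the ideal DCG zero, in
which case NDCG is defined as 0 with a warning instead of crashing a batch
run — a package decision for a case the measure's definition leaves open.

## Models

**Kernel ridge / RKHS regression.** The dual solution
$\alpha = (K + \lambda I)^{-1} y$ with $K_{ij} = \kappa(x_i, x_j)$ costs
$O(n^3)$ instead of $O(p^3)$ and allows nonlinear kernels; with the linear
kernel it is exactly primal ridge ($\beta = X^\top\alpha$), the equivalence
the tests verify to $10^{-6}$ in both the $n > p$ and $n < p$ regimes.
`fit_rkhs()` fits the trait mean as a fixed intercept (solve on the
centered trait, add the mean back at prediction), as mixed-model BLUP
implementations do; without it a constant trait offset — such as the
nonnegativity shift — would have to be absorbed by marker effects and
distorts the fit. The raw uncentered solver remains available as
`fit_kernel_ridge()` / `fit_rkhs(intercept = FALSE)`. Regularization (and
the RBF scale) are tuned by grid cross-validation on 15 log-spaced values
of $\lambda$ in $[10^{-6}, 10^6]$; restricted-maximum-likelihood
auto-tuning, the other common convention for this model, is deliberately
out of scope, and this substitution is flagged rather than claimed
equivalent.

**Kernel RankSVM** (pairwise) minimizes
$f(\alpha) = \tfrac{\lambda}{2}\alpha^\top K \alpha +
\sum_{(i,j) \in P} \max(0,\, 1 - \alpha^\top K_i + \alpha^\top K_j)^2$,
the squared-hinge ranking loss over preference pairs, with gradient
$\lambda K \alpha + 2\sum_{(i,j) \in P} \max(0, 1 - \alpha^\top K_i +
\alpha^\top K_j)(K_j - K_i)$. The objective is strictly convex, so the
minimizer is unique. Solver choices: limited-memory BFGS from
$\alpha = 0$ (where $f(0) = |P|$ exactly), a 500-iteration cap, and a
projected-gradient tolerance of $10^{-5} n$. Regularization follows the
$\lambda = |P|\,\tilde{\lambda}$ convention so $\tilde{\lambda}$ grids
transfer across sample sizes. The pair sum in the gradient collapses to
$K u$ for an accumulation vector $u$, so one evaluation costs
$O(n^2 + |P|)$. The linear variant of the hinge (exponent 1) is not
implemented: it is nondifferentiable and would need a subgradient method.
For the RBF kernel $\kappa(x_i, x_j) = \exp(-\gamma\lVert x_i - x_j
\rVert^2)$ the width is parameterized as $\gamma = 1/(4 p \sigma^2)$ with
$\sigma$ tuned on $\{0.1, \dots, 1.0\}$; $\sigma = 0$ is excluded because
$\gamma$ would be undefined there.

**McRank** (pointwise) discretizes the training trait into $B$ equal-width
bins with means $b_1 \le \dots \le b_B$ and ranks candidates by the
expected trait value $h(x) = \sum_r \Pr(y = b_r \mid x)\, b_r$. Bin
intervals are left-closed/right-open with the last bin closed; empty bins
are dropped and $B$ reduced, so every bin mean is well defined. The
multiclass variant fits one probabilistic classifier over bins; the
ordinal variant fits $B - 1$ binary threshold classifiers for the
cumulative probabilities $\Pr(y \le b_r \mid x)$ and differences them,
respecting the bin ordering. Because the threshold classifiers are
independent, the estimated cumulative curve can be non-monotone; negative
differences are clipped at zero and the probability vector renormalized to
sum one — the minimal repair that preserves a valid distribution, chosen
as a package convention since the method's description leaves the case
open. The default classifier is a random-forest probability learner
(`ranger`), selected because tree ensembles handle the 0/1/2 feature space
well; any object with the same `fit`/`predict_prob` surface can be
substituted, and the bin count is tuned on $\{3, \dots, 20\}$.

**GBRT and LambdaMART** (listwise). Gradient-boosted regression trees start
from the trait mean and fit each stage tree to the current residuals, with
the exact squared-loss line-search weight shrunk by a learning rate;
training MSE is provably non-increasing for rates $\le 1$. LambdaMART keeps
the boosting machinery but replaces residuals with $\lambda$-gradients: for
each preference pair, $\lambda_{ij} = |\Delta\mathrm{NDCG}_{ij}| \cdot
1/(1 + e^{s_i - s_j})$, the NDCG change from swapping the two individuals
in the current ranking times a logistic derivative of their score
difference; the preferred individual receives $+\lambda_{ij}$ and the
other $-\lambda_{ij}$. Two conventions here deserve a note. First, the
sign: some formulations write a $\mathrm{sign}(s_i - s_j)$ factor, which
contradicts the accompanying interpretation that the preferred individual
is always pushed up; this package follows the interpretation
(label-ordered pushes with antisymmetry $\lambda_{ji} = -\lambda_{ij}$, so
$\sum_i \lambda_i = 0$ always). Second, $\Delta\mathrm{NDCG}$ is
normalized by the ideal DCG so stage targets are scale-free across traits;
the swap change reduces to
$|(g_i - g_j)(d(\mathrm{pos}_j) - d(\mathrm{pos}_i))|$ with the discount
truncated to zero beyond position $k$, hence pairs ranked entirely below
$k$ contribute exactly nothing. Stage trees enter with weight equal to the
learning rate alone — there is no primitive objective to line-search, so
the conventional choice for $\lambda$-gradient boosting is used. Stage
trees are a hand-written CART (variance-reduction splits, leaf means) with
per-split feature subsampling `max_features` and a depth cap, because no
installed tree learner exposes per-split subsetting with injectable
determinism; defaults are 300 trees, `max_features = 0.6`, depth tuned on
$\{3, 5, 10\}$, learning rate on $\{0.001, 0.01, 0.1, 1.0\}$ with 0.1 the
rule-of-thumb default. Random forests (regression baseline and McRank's
classifiers) are delegated to `ranger`, run single-threaded so a seed
fully determines the forest.

## The benchmarking protocol

Each dataset is split at random into 80% for model estimation and 20% for
evaluation, 10 times; all methods see identical splits (the split sequence
is a function of data size, seed and iteration only). Hyper-parameters are
selected by 5-fold cross-validation *within* each training split,
maximizing the same measure later used for evaluation (minimizing for
MSE); ties break toward the earlier grid point and a grid point that fails
on any fold is scored as worst rather than aborting. A method failure on
an outer split is recorded as missing and excluded from averages with a
warning. Outer splits are simple random draws without stratification.
Aggregation follows the same constructions used for multi-dataset studies:
per-measure average ranks across datasets (average ranks on ties) and a
measure-agreement matrix of Spearman correlations between per-method score
vectors, averaged across datasets, with MSE negated first so that "better"
points the same way for every measure.

## The synthetic generator

`simulate_genotypes()` draws each marker's allele frequency uniformly from
`maf_range` and genotypes as two independent allele draws (Hardy–Weinberg
proportions, no linkage disequilibrium); `simulate_trait()` picks `n_qtl`
causal markers, draws standard-normal additive effects (optionally plus
pairwise products of consecutive QTL genotypes), and adds normal noise with
variance $\mathrm{var}(g)(1 - h^2)/h^2$ so the genetic fraction of trait
variance equals the requested heritability; traits are shifted nonnegative
at generation. Genotypes, effects and noise use independent derived seed
streams, so changing the heritability leaves the genotypes untouched. This
emulates what the methods assume — sparse additive architecture, $n \ll p$,
a heritability ceiling $\sqrt{h^2}$ on achievable correlation — and
deliberately not what real panels add: linkage disequilibrium structure,
multi-allelic QTL, population stratification, genotype-by-environment
interaction. Passing tests on simulated data therefore demonstrate
correctness of the machinery and recovery under the assumed model, not
field performance. Default scale is `n = 400`, `p = 2000`, 20 QTL,
`h2 = 0.6`.

## Problem sizes used in tests

The shipped test suite exercises the full protocol at deliberately modest
sizes chosen to make the properties sharp rather than the datasets large:
the noiseless-recovery check runs `n = 200`, `p = 50`, 10 QTL, $h^2 = 1$
over 10 simulated datasets with the complete 80/20 × 10 harness and fixed
hyper-parameters (ridge $\lambda = 1$, RankSVM $\tilde{\lambda} = 10^{-3}$,
linear kernel — at $h^2 = 1$ the signal is exactly linear and tuning adds
nothing, while the tuning machinery itself is tested separately on small
grids); the heritability-ceiling check uses `n = 1000`; measure identities
use thousands of small random instances. Exhaustive enumerations (all 720
orderings of six individuals for DCG optimality) are preferred over
sampling wherever feasible.

## Known limitations

- No genotype imputation or allele-frequency filtering: missing genotype
  cells are an error by design, and input tables are expected clean.
- No VCF/PLINK parsing; convert with e.g.
  `plink --recode A` / `bcftools query` to a 0/1/2 CSV first.
- Kendall's $\tau$ here is the strict-preference form, not $\tau_b$.
- LambdaMART inherits the known weakness of $\lambda$-gradient boosting
  when $n \ll p$; it is included as a listwise representative, not as a
  recommendation.
- The Bayesian shrinkage regressions often benchmarked in this field
  (Bayesian lasso variants, spike-and-slab, mixtures) are out of scope.
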