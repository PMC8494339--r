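---
title: "Gene selection by bias-corrected mutual information and complementary information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection by bias-corrected mutual information and complementary information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgsel)
```

## The problem

Disease expression studies typically measure tens of thousands of genes on a
few dozen samples. Only a handful of genes discriminate the conditions
(control vs disease), and finding them is complicated by three things:
mutual-information estimates from so few samples are biased upward; the right
granularity at which to discretize a continuous expression profile differs
from gene to gene; and genes work in pathways, so two genes with correlated
expression can *both* be informative — a selection rule that discards
"redundant" genes throws away biology.

`mgsel` addresses all three. It scores genes by mutual information with the
class after subtracting the finite-sample bias, picks each gene's
discretization level dynamically by significance, and — unlike
minimum-redundancy selectors — rewards *complementary* (class-conditional)
information between genes instead of penalizing their unconditional
correlation.

## Relevance and its bias correction

For gene $g_i$ discretized into $d_i$ bins the corrected relevance is

$$J_{rel}(g_i) = I(g_i^{d_i}; C) \;-\; \frac{(I-1)(K-1)}{2N\ln 2},$$

where $I$ is the number of *occupied* bins, $K$ the number of classes and $N$
the sample count. The subtraction is exact for the asymptotic null: under
independence $2N\ln 2 \cdot I(X;C)$ is $\chi^2$ with $(I-1)(K-1)$ degrees of
freedom, so the empirical MI (in bits) has null mean $(I-1)(K-1)/(2N\ln 2)$.
We use occupied rather than nominal bin counts because empty cells contribute
no degrees of freedom to the $\chi^2$ null; with few samples and many bins
the two differ substantially.

Significance is judged against the $\chi^2$ critical value placed on the same
corrected bit scale:

$$j > \frac{\chi^2_{1-\alpha}(df) - df}{2N\ln 2}
  \iff 2N\ln 2 \cdot I(X;C) > \chi^2_{1-\alpha}(df),$$

so the default `critical_scale = "corrected"` is algebraically the standard
raw-scale test. A `"literal"` mode that rescales the quantile without
subtracting $df$ is available; it is stricter by exactly the bias term. The
default $\alpha = 0.05$ is the conventional level; no threshold other than
this significance level is hand-tuned anywhere in the method.

## Screening: the minimal significant level

`screen_candidates()` sweeps $d = 2, \dots, max_d$ for every gene and keeps
the *first* level at which $J_{rel}$ passes its test (with that gene's
score and level recorded). Defaults are $max_d = 10$ and equal-width bins
over the observed range — the simplest convention consistent with "a gene at
$d$ levels"; equal-frequency binning is available via `mgs_config(scheme=)`.
Equal-width bins at $n \approx 20\text{–}250$ samples keep occupied counts
low, which the bias and df formulas then reflect.

One statistical consequence deserves emphasis: each *level* test has size
$\alpha$ (our null simulations measure 0.048–0.066 per level at $n = 100$),
but a gene passes screening if *any* level in the sweep passes, so the
per-gene false-candidate rate of the sweep is a union over correlated tests —
roughly 17% over $d = 2..5$ and near 29% over $d = 2..10$ at desk scales,
not $\alpha$. The greedy criterion below prunes most of these again. Users
who need a per-gene family-wise rate of $\alpha$ can set `max_d = 2` or
lower `alpha`.

## Selection: complementary information, no redundancy penalty

Candidates are sorted by decreasing relevance (ties by original gene order)
and the top gene seeds the selected set $G_S$. Each remaining candidate is
evaluated by

$$J(g_i) = J_{rel}(g_i) + \frac{1}{|G_S|}\sum_{g_s \in G_S}
  \left[ I(g_i; g_s \mid C) - \frac{(I-1)(J_s-1)K}{2N\ln 2} \right],$$

the corrected relevance plus the *mean* corrected conditional mutual
information with the already-selected genes. Note what is absent: any
penalty on $I(g_i; g_s)$. Correlated informative genes (co-regulated pathway
members) are retained; a gene is admitted whenever it is significantly
relevant *and/or* carries additional class-conditional signal.

Because screening fixed each candidate's level from the marginal criterion
only, the level is re-examined during selection: every $d \in
[d_i - \delta,\, d_i + \delta]$ (clamped to $[2, max_d]$; default $\delta =
2$) is tried and the candidate is admitted if $J$ exceeds its critical value
at *any* level, keeping the passing level with maximal $J$. Keeping the
maximum matches the intent of the sweep — find the granularity at which the
joint structure is strongest; a variant that keeps the last passing level
exists in the literal mode below.

**Degrees of freedom for the composite test.** $J$ is a sum of a relevance
term and a mean of complementary terms, each asymptotically $\chi^2$ under
its null with dfs $(I-1)(K-1)$ and $(I-1)(J_s-1)K$. We test $J$ against
$\chi^2$ at the composite df

$$df_J = (I-1)(K-1) + \frac{1}{|G_S|}\sum_s (I-1)(J_s-1)K,$$

mirroring the construction of the statistic itself. This is deliberately
conservative: a mean of $m$ $\chi^2_f$ variables is more concentrated than
$\chi^2_f$, so as $G_S$ grows the test under-rejects slightly. The
consequences are measurable on synthetic data (below): marginally
informative genes are occasionally dropped at the admission stage even when
screening found them, and genuinely null candidates are pruned hard.

**Literal pseudocode mode.** The natural transcription of the greedy loop
initialises a threshold $T \leftarrow 0$ and a running score $j_i$ with the
candidate's screening relevance, updates both only when a sweep level passes,
and finally admits the candidate if $j_i > T$. If *no* level passes, $j_i$
still holds the (positive) screening relevance and $T$ is still 0 — so the
final comparison admits every candidate regardless of the test. The package
default is the strict reading (admit only if the test passed);
`mgs_config(literal_algorithm1 = TRUE)` reproduces the literal behaviour
exactly, including keeping the last rather than the best passing level. A
unit test pins the difference.

## Ranking

Selection runs once per cross-validation fold, and the per-fold subsets are
aggregated into a union $G_{SU}$ with per-gene selection frequencies $F_i$.

- **Frequency ranking** (`rank_by_frequency()`): score $P(S_i) = F_i /
  |G_{SU}|$ — genes selected in every fold are the most trustworthy.
- **Forest ranking** (`rank_by_forest()`): an $M$-tree random forest
  (default $M = 300$) of entropy-criterion decision trees is fitted to the
  data restricted to $G_{SU}$; every internal node contributes a record
  $(g, \mathrm{IG})$ with

  $$\mathrm{IG} = \frac{N_t}{N}\left[H(\text{parent}) -
    \frac{N_L}{N_t}H(\text{left}) - \frac{N_R}{N_t}H(\text{right})\right],
    \qquad H = -\sum_i P_i \log_2 P_i,$$

  and a gene's score is the mean IG over the nodes that split on it (0 for
  genes never used). This forest is purpose-built — node-level entropy gains
  are the quantity being averaged, and off-the-shelf forest importances
  (Gini decrease, permutation) are different statistics. It is also kept
  separate from the random-forest *classifier* used in evaluation, which
  comes from the `randomForest` package. Forest hyperparameters besides $M$:
  unlimited depth, $\lceil\sqrt{|G_{SU}|}\rceil$ features per node, bootstrap
  resampling, mandatory seed.

Ties in either ranking are broken by descending mean training-fold relevance
when available, then by gene id in natural order (alphabetic prefix, numeric
suffix) — both deterministic. `top_eta()` takes the first $\eta$ genes
(default $\eta = 10$) as the biomarker panel, or all of them when fewer were
selected.

## Evaluation protocol

`mgs_evaluate()` follows a nested design. Outer folds: leave-one-out when
$n < 100$, stratified 10-fold otherwise ($K = 10$ is the community default;
both the threshold and $K$ are arguments). Within each outer fold the
*training split only* is given to an inner cross-validation (same rule) that
produces the per-fold selections, their union, the ranking and the top-$\eta$
panel; the classifier — linear-kernel SVM (`e1071`) or 300-tree random
forest (`randomForest`), library-default hyperparameters — is fitted on the
training split restricted to the panel and scored on the held-out samples.
Nothing computed from a test split ever reaches selection, ranking or
fitting; a canary test corrupts a held-out label and verifies the fold's
panel is bit-identical.

Accuracy is the mean over folds. For AUROC, leave-one-out folds have a
single test sample and no ROC of their own, so scores are pooled across
folds before the curve is computed; under $K$-fold the per-fold AUROCs are
averaged. The report records which convention was used. AUROC itself is the
midrank Mann–Whitney statistic, verified against brute-force pair counting.

## The synthetic benchmark

`generate_synthetic()` produces datasets with known ground truth. Defaults —
60 samples, balanced Bernoulli classes, 10 informative genes shifted by 1.5
SD, 2 redundant copies of each (additive noise SD 0.3), 3 XOR pairs, 2000
noise genes — are a desk-scale caricature of a small disease study: enough
genes to make false positives matter, few enough samples that finite-sample
bias is material. XOR pairs are two ±1 coin genes whose exclusive-or is the
class, jittered with Gaussian noise (SD 0.1) so they pass through the real
discretizer rather than arriving pre-binned; each is marginally independent
of the class while the pair is jointly deterministic, which is precisely the
structure the conditional-MI term can reward.

What the generator does *not* emulate: probe-level microarray artifacts,
batch effects, heavy-tailed or count-distributed expression, correlated
noise between unrelated genes, and class-dependent variance. Passing tests
on this benchmark therefore demonstrate the machinery (calibration, power at
a stated effect size, leak-freedom), not performance on any real cohort.

Two honest findings from the benchmark at its default settings, both
reproduced by `scripts/acceptance.R`:

- *All-informative recovery is high but not near-certain.* Screening finds
  every planted informative gene essentially always, but the conservative
  composite-df admission test drops a marginal one now and then
  (per-gene retention ≈ 98%), so the probability that *all ten* survive in a
  replicate is ≈ 0.85–0.95 rather than ≳ 0.95.
- *XOR pairs are not rescued by greedy selection.* The complementary term
  rewards an XOR gene only when its partner is already selected, but each
  partner is marginally independent of the class and reaches the candidate
  pool only at the null rate — so joint candidacy is rare, and XOR genes
  that do arrive alone are pruned like noise (retention ratio ≈ 1, not ≫ 1).
  This is a structural property of any pairwise greedy criterion seeded by
  marginal relevance: it can exploit complementary structure among genes it
  has already found, but cannot bootstrap a pair that is invisible
  marginally. A unit test shows the flip side: once one XOR gene is in
  $G_S$, its partner passes the admission test decisively.

## Numerical choices and degenerate inputs

- All information quantities are in bits (`log2`), matching the $\ln 2$
  factors in the bias terms; $0\log 0 = 0$ throughout.
- Constant genes discretize to a single occupied bin, have zero MI and zero
  df, and can never become candidates.
- The maximum value of a gene is assigned to the top equal-width bin.
- Missing cells are `NA` on input (never zero); probe collapsing averages
  over observed values only; genes entirely missing are dropped; remaining
  gaps are filled with the per-gene median (deterministic, robust), and
  imputation can be disabled.
- Duplicate-symbol probe rows are merged by unweighted arithmetic mean on
  the raw scale.
- Class strings map to codes by sorted order; the larger code is the
  positive class in evaluation reports.
- Seeds are mandatory wherever randomness exists (fold shuffles, forests,
  generators); results are bit-reproducible given (data, config, seed).

## Problem sizes used by the test suite

The suite keeps everything at desk scale by choice: null calibration uses
2000 simulated gene–label pairs at $n = 100$; oracle cross-checks use 200
random contingency-table instances; the recovery study runs 50 replicates of
the default generator; end-to-end evaluations use 14–20 samples and up to a
few hundred genes under leave-one-out. These sizes exercise every code path
(including the vectorized screening against the scalar definition) while the
whole suite completes in a few minutes.

## Known limitations

- The greedy, pairwise criterion cannot discover purely joint (XOR-like)
  structure, as quantified above; higher-order terms would be needed.
- The composite-df $\chi^2$ test for the selection criterion is heuristic
  and conservative; its null is not exactly $\chi^2$.
- The screening sweep's per-gene false-candidate rate exceeds $\alpha$ by
  construction (union over levels); downstream pruning compensates only
  partially.
- Expression input is taken as provided — no normalization or log transform
  is applied, and probe collapsing on the raw scale is an assumption.
- Under leave-one-out, pooled-score AUROC mixes decision values across
  training sets of slightly different composition; per-fold AUROC is
  undefined there, so this is a trade-off rather than a bug.
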