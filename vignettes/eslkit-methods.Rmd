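---
title: "Evolutionary sparse learning with eslkit: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary sparse learning with eslkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eslkit)
```

## The model

Evolutionary sparse learning (ESL) treats a binary evolutionary hypothesis —
membership of a focal clade, or presence of a trait — as the response of a
supervised learning problem, and the variation in a multiple sequence
alignment as the predictors. Each alignment position contributes one binary
*bit column* per character state observed there; a taxon's row holds a 1 in
the bit column matching its character. Bit columns are partitioned into
mutually exclusive *groups*, one per input alignment file (a gene, protein,
exon or any user-defined set of sites).

With taxa labeled $y_i \in \{+1, -1\}$ and encoded rows $x_i$, eslkit fits a
logistic regression under a bi-level (sparse group LASSO) penalty:

$$
L'(\beta) \;=\; \frac{1}{\sum_i w_i}\sum_i w_i
\log\!\left(1 + e^{-y_i (x_i^\top \beta + c)}\right)
\;+\; \lambda_1 \lVert\beta\rVert_1
\;+\; \lambda_2 \sum_g w_g \lVert\beta_g\rVert_2 ,
$$

where $c$ is an unpenalized intercept, $w_i$ are sample weights (used for
class balancing and replicates), and $w_g$ defaults to the square root of
the number of bit columns in group $g$. The $\ell_1$ term zeroes individual
bit columns; the grouped $\ell_2$ (not squared) term zeroes whole groups, so
a fitted model names both the loci and the sites within them that carry
variation concordant with the hypothesis. We use the Euclidean group norm,
the standard sparse-group-LASSO form.

Normalizing the loss by total weight keeps the penalty scale comparable
across dataset sizes, so the same user-facing $\lambda$ means roughly the
same thing on 20 or 2,000 taxa.

## Encoding and filtering

Character validity is governed by a data-type policy: `nucleotide`
(A/T/C/G/U, case-insensitive), `protein` (the 20 unambiguous IUPAC amino
acids, case-insensitive), `molecular` (their union) and `universal` (all
letters case-sensitively, plus digits, for presence/absence or epigenetic
codings). Gaps (`-`), `?` and any character outside the policy are treated
as missing and never receive a bit column; IUPAC ambiguity codes in
nucleotide mode are therefore missing data.

Three filters run in a fixed order on the taxa selected for the analysis:

1. **Monomorphic positions** (all valid characters identical, ignoring
   missing) are dropped — they carry no signal. A position with no valid
   character at all is dropped the same way.
2. **Singleton bit columns** (exactly one taxon carries the 1) are dropped
   unless `include_singletons = TRUE`; a private state in one taxon cannot
   generalize.
3. Bit columns with fewer than `bit_ct` ones are dropped (`bit_ct = 1` by
   default, i.e. inactive), a memory-control knob for very long alignments.

Applying the monomorphic filter before the singleton filter makes
`bit_ct = 2` a strict superset of singleton removal. When all of a
position's minority characters are singletons we drop only those columns,
not the whole position.

## Hypotheses and class balancing

A hypothesis comes either from a two-column class file or from a rooted
Newick tree in which a labeled internal node marks the focal clade (its
leaves become +1, all others −1). Unrooted trees are rejected rather than
silently midpoint-rooted, because the +1 class is defined by a rooted
subtree. Candidate clades can be enumerated over all non-root internal
nodes, with clade-size cutoffs; unlabeled nodes get deterministic
`node_<preorder index>` labels so runs are reproducible. The root is never
a candidate (its contrast class would be empty).

Four balancing strategies address unequal class sizes:

- **up**: minority taxa resampled with replacement, realized as integer
  replicate counts — the loss is identical to physically duplicated rows
  (verified in the tests to 1e-8).
- **down**: uniform subsample of the majority class without replacement.
- **weighted**: weight $n/(2 n_c)$ per taxon of class $c$; both classes
  then contribute equal total weight and no taxa are dropped.
- **phylo**: negatives are collected from progressively more distant sister
  groups of the focal clade, stopping once the −1 class is at least as
  large as the focal clade; a surplus is trimmed starting with the taxon
  most distant from the focal node. Distance is patristic when the tree
  has branch lengths and edge-count otherwise, with reverse-alphabetical
  tie-breaking — the tie-break is arbitrary but fixed, because
  reproducibility matters more than the particular choice. If the focal
  clade itself must shrink (more positives than available negatives), a
  prominent warning is emitted since that distorts the hypothesis under
  test; weighted balancing is the better tool there.

Balancing runs before fold assignment in cross-validation, so upsampled
replicates of one taxon can occur on both sides of a split; with heavy
upsampling, holdout accuracies are therefore optimistic.

## Solver

The objective is minimized by FISTA (accelerated proximal gradient) with
backtracking line search. The proximal operator of the combined penalty has
the Moreau–Yosida closed form: elementwise soft-thresholding by
$t\lambda_1$ followed by per-group block soft-thresholding by
$t\lambda_2 w_g$, which produces exact zeros — sparsity in the reported
models is structural, not a rounding threshold. The intercept is
unpenalized and updated inside the smooth gradient step. Whenever the
accelerated step would increase the objective, the solver falls back to a
plain proximal step from the last accepted iterate and restarts the
momentum, so the objective trace is non-increasing by construction; the
test suite asserts this on every fitted problem.

Numerical choices: $\beta = 0$ and $c = \log(W_+/W_-)$ at initialization
(deterministic, so fits need no seed); convergence when the relative
objective change drops below `tol` (default 1e-6, tightened to 1e-13 in
oracle-comparison tests); `max_iter` 10,000; the local Lipschitz estimate
is halved each iteration and doubled during backtracking. The logistic
terms use a guarded `log1p(exp(x))` so large margins cannot overflow.

### Penalty normalization

Users give $\lambda_1, \lambda_2 \in [0, 1]$. Each is scaled by its own
critical value: $\lambda_1$ by $\lambda_{\max}$, the smallest absolute
$\ell_1$ penalty at which $\beta = 0$ is optimal when $\lambda_2 = 0$
(the largest absolute gradient coordinate at the null model), and
$\lambda_2$ by the analogous group-level quantity
$\max_g \lVert \nabla_g \rVert_2 / w_g$. This symmetric normalization is a
deliberate design choice: scaling both penalties by the $\ell_1$-scale
$\lambda_{\max}$ makes the group term degenerate in practice — on our
planted benchmark every group is already eliminated near
$\lambda_2 \approx 0.2$, so most of the nominal $[0, 1]$ range does
nothing and the 0.1 default sits at the edge of total sparsity. Under the
symmetric scaling, $\lambda_1 = 1$ (at $\lambda_2 = 0$) and
$\lambda_2 = 1$ (at $\lambda_1 = 0$) are each exactly the smallest values
that zero the whole model, and the defaults of 0.1 for both sit in a
usable part of the path. Consequently absolute penalty values are not
comparable with implementations that scale differently; properties of the
solution path (support monotonicity, the null-model limit, oracle
equivalence at $\lambda = 0$) are what we verify.

With `--no_group_penalty`, or when only a single alignment file is given,
the group term is dropped and the fit is a plain $\ell_1$ logistic LASSO
(checked against glmnet to 1e-4 in the tests).

## Scores and outputs

For a fitted model, the sequence prediction score of a taxon is
$SPS = x^\top\beta + c$ and its probability $SPP = 1/(1 + e^{-SPS})$;
$SPS \ge 0$ classifies into the focal class. Sparsity scores are additive
absolute-coefficient sums: $PSS$ of a position is $\sum |\beta|$ over its
bit columns, $GSS$ of a group the sum of its positions' $PSS$, and $HSS$
the sum over groups, with exact additivity by construction. The intercept
is excluded from $HSS$ — it encodes class imbalance, not sequence signal.
An optional normalization divides position and group scores by $HSS$ for
comparability across models. Model files list only nonzero-coefficient
columns, with full-precision numbers so a write–read round trip reproduces
predictions bitwise; instead of a raster grid image, a per-taxon-by-group
contribution table ($\sum x\beta$ within each group) is written as TSV.

Grid search fits every pair on inclusive $(\min, \max, \text{step})$
lattices and retains models by three rules: RMSE at most the cutoff
(RMSE is computed between $SPP$ and 0/1 labels, hence bounded by 1, which
makes the default cutoff of 100 a deliberate no-op), training accuracy at
least 0.95 by default, and at least `min_groups` selected groups.
Cross-validation is stratified: per-class seeded shuffle, then
round-robin, so per-fold class counts never differ by more than one from
perfect balance.

## The synthetic generator

`make_planted_dataset()` writes a complete miniature study: a balanced
rooted tree whose first half of taxa is the labeled focal clade, one FASTA
per group, a class file and list files. Designated informative positions
carry one fixed state inside the clade and a different state outside;
every other cell is uniform over the alphabet, with an optional fraction
replaced by gaps. Noise positions are i.i.d. uniform — there is no
substitution model, no rate heterogeneity, no phylogenetic autocorrelation
in the noise, and no alignment error. Passing tests on these fixtures
demonstrates that the machinery recovers a planted signal and rejects
exchangeable noise; it does not demonstrate robustness to the correlated
variation, saturation and model misspecification of real phylogenomic
data.

The benchmark configuration used throughout the tests and the acceptance
script is 20 taxa, 5 groups of 50 sites, 2 informative sites in the first
group (about 1,000 bit columns), with a 10-taxon variant for
cross-validation; these sizes keep the full suite fast while leaving the
planted-recovery problem non-trivial (at 20 taxa, spurious noise
correlations are substantial, which is exactly what the sparsity penalty
must reject).

## Known limitations

- Positions are assumed to correspond across training and prediction
  alignments; the apply pipeline checks only per-group lengths, not
  homology. No profile alignment of new sequences is performed.
- The group partition must be non-overlapping; overlapping or nested
  groupings (e.g. codon within gene) are out of scope.
- Only logistic loss is implemented; no least-squares mode, elastic net or
  model averaging across retained grid cells.
- Absolute $\lambda$ values are implementation-specific (see the
  normalization note above); compare models by their selection paths, not
  by raw penalty values.
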