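---
title: "Boolean Equivalent Correlated Clusters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean Equivalent Correlated Clusters: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A universal biomarker of a cell type (say, tissue macrophages) should be
expressed in every subpopulation of that cell type, in every tissue. In bulk
expression data such a gene's measurement is proportional to the abundance of
the cell type in the sample, so two genuine universal markers are tightly
correlated across *any* large, heterogeneous compendium: both low where the
cell type is absent, both high — and linearly related — where it is present.
`beccr` operationalises this idea as a pipeline over log2-scale expression
matrices (probes × samples): binarise each probe, find probes whose binary
patterns are mutually implied, expand from a trusted seed marker, then rank
the candidates by how strongly each one co-varies with the whole cluster.

## Step fits and booleanization

For each probe the values are sorted ascending and a rising one-step function
is fitted: samples `1..k` modelled by their mean `mu_low`, samples `k+1..n`
by `mu_high`, with `k` chosen to minimise the residual sum of squares over
all `n - 1` positions (`fit_step()`; prefix sums make this a single pass).
The midpoint `(mu_low + mu_high)/2` is the threshold. An F statistic
`(ssr/(m-1)) / (sse/(n-m))` is reported for diagnostics. The fit has two
segment means and one break position, so `m = 3` by default; nothing
downstream consumes the F value, the threshold is what matters, so `m` is a
configurable reporting choice rather than a modelling one.

Numerical choices: ties on the SSE break to the smallest `k`; a constant
vector is degenerate (threshold equals the value, `fstat = Inf`, flagged);
missing values are dropped before fitting. `booleanize()` then calls a value
LOW below `threshold - margin`, HIGH above `threshold + margin`, and
INTERMEDIATE otherwise. The default margin of 0.5 log2 units is a
twofold-change noise band. Values landing exactly on a margin boundary are
kept INTERMEDIATE — the conservative choice, since intermediate samples are
excluded from all downstream counting and a boundary value carries no
reliable state.

## Boolean implication statistics

For a probe pair, the samples where both calls are LOW or HIGH populate four
quadrants with counts `a00, a01, a10, a11` (first index = probe A). Under
independence the expected count of quadrant `(i, j)` is
`nhat = nA_i * nB_j / total`. A quadrant is *sparse* when

* `S = (nhat - n) / sqrt(nhat) > 3`, and
* `p = (a_ij/nA_i + a_ij/nB_j) / 2 < 0.1`,

with strict inequalities. `p` generalises the printed bottom-left form to
every quadrant as the mean of the two conditional probabilities of landing
there; at `(0,0)` it reduces exactly to
`(a00/(a00+a01) + a00/(a00+a10))/2`. Both off-diagonal quadrants sparse
means the genes are high together and low together (EQUIVALENT); both
diagonal quadrants sparse means OPPOSITE; a single sparse quadrant gives one
of the four asymmetric implications (sparse `(0,0)` is "A low ⇒ B high",
`(0,1)` "A low ⇒ B low", `(1,0)` "A high ⇒ B high", `(1,1)` "A high ⇒ B
low").

Degenerate inputs are resolved as follows. A quadrant with `nhat = 0` has a
zero marginal (and hence a zero observed count); sparsity cannot be attested
without an expectation, so it is treated as non-sparse. Two *adjacent*
sparse quadrants, or three or more, have no defined relation and classify as
NONE with an `"ambiguous"` diagnostic flag. Pairs with fewer than 20
informative samples are NONE (`min_total`, configurable): below that total
the expected counts cannot exceed ~5, so `S > 3` is close to unattainable
anyway and small-sample flukes are cut off explicitly.

## Seed expansion and scoring

`expand_seed()` grows the network in rounds: set A is every probe
Boolean-equivalent to the seed; B adds probes equivalent to at least one
member of A; C repeats once more. Three rounds is the default — later rounds
mostly admit noise. The seed is excluded from the reported sets (so set
sizes count the seed's companions) and appended to the final candidate list
L. A seed whose calls are one-sided is rejected with an error; a seed with
no equivalents yields an empty result with a warning, which is a meaningful
outcome: markers without equivalence structure simply fail the method.

Every pair in L is then scored on the raw log2 values (not the Boolean
calls — correlation and regression need the quantitative signal):
`score = r^2 + s^2`, with `r` the Pearson correlation floored at 0 and `s` a
regression slope with the reciprocal taken when above 1, so `score` lies in
`[0, 2]`. The slope of B on A and of A on B differ on noisy data, and the
reciprocal rule alone does not reconcile them; `pair_score()` computes both,
applies the reciprocal rule to each, and keeps the smaller. This makes the
score exactly symmetric in its arguments (so the score matrix `M` is
symmetric by construction, as its row-sorting usage presumes), reduces to
`min(c, 1/c)` for an exact linear relation `B = cA`, and is mildly
conservative otherwise. The diagonal of `M` is the self-score 2 and is
included in every row's sort — it adds the same top-rank term to every row
and cannot reorder probes, while keeping the rank sum running over
`k = 0 .. len(L)-1` exactly as defined:

`gs_i = (1/len(L)) * sum_k k * score_(k) / 2`,

where `score_(k)` is the k-th smallest score in row i. `gs` is bounded by
`(len(L)-1)/2`. A StepMiner fit on the sorted `gs` values supplies the
selection threshold; probes strictly above it are the result. Ties in the
output report break lexicographically by probe id so reports are
deterministic.

## The empirical null and its approximations

`empirical_null()` samples distinct probe pairs uniformly without
replacement from the whole matrix (default 100000 pairs, seeded), scores
them, and converts the moments to a null for `gs`:
`E[gs] = E[score]*(len(L)-1)/4` and `sd(gs) = sqrt(Var[score])*(len(L)-1)/4`,
followed by a one-sided upper-tail Z-test of the selection threshold (high
scores are the signal, so the test is one-sided).

Both conversions treat the k-th smallest score in a row as an exchangeable
draw from the score distribution. That is an approximation: for the mean,
`E[sum_k k * score_(k)] = C(len, 2) * E[max(s1, s2)]`, which exceeds
`C(len, 2) * E[score]` for any non-degenerate score distribution, so the
analytic `E[gs]` underestimates the simulated mean of rank-weighted sorted
iid scores — by roughly 80% in relative terms for the score distributions
the default compendium produces. The variance formula inherits the same
issue for a weighted sum of dependent order statistics. The package
implements the formulas as defined and exposes the raw sampled scores
(`null$scores`) so the approximation can be quantified by simulation, as the
test suite and the acceptance script both do. In practice the Z values of
genuine clusters are enormous (≈ 68 on the default synthetic compendium)
and the bias is immaterial to the accept/reject decision, but the reported
`E[gs]` should be read as a lower bound.

## Validation statistics

* `high_high_fraction()` — fraction of samples with both genes strictly
  above their thresholds. The default midrange threshold is the midpoint of
  the dataset-wide observed value range, the same convention as marker
  scatterplots whose shared axis limits (and midpoint reference lines) come
  from the range observed across genes. This matters on purified-cell data:
  every sample is in the high state, a per-gene midrange would fall inside
  the high cluster and report ~25% co-expression for a perfect marker pair.
  Per-gene ranges (`range_basis = "gene"`), explicit ranges, and StepMiner
  thresholds are available; the boundary case (value equal to the threshold)
  counts as low, since the reference-line convention does not define it.
* `variance_ftest()` — two-sided variance-ratio F-test via
  `stats::var.test()`, reported with `F = larger/smaller >= 1`. A universal
  marker should have low variance on purified data; subset markers are
  bimodal there and fail this test.
* `correlation_ranking()` — Pearson correlation of candidates against a
  reference, sorted descending, ties by gene id, undefined correlations
  (constant genes) last.

## The synthetic compendium

`generate_compendium()` plants known structure so every stage is testable
without external data. Per sample a latent target-cell abundance `f` is
drawn: 60% of samples near zero (`U(0, 0.02)`), a small fraction (2%)
exactly pure (`f = 1`), the rest `U(0.05, 1]`. This reproduces the dense
low-low corner plus a diffuse high arm seen in real compendium
scatterplots. Universal probes emit the high state when `f > 0.05`, i.e.
whenever target cells are present; subset probes require in addition a
per-sample subset program flag (Bernoulli, prevalence 0.4 among target-high
samples — a shared flag, modelling a coherent subtype); noise probes are
iid bimodal with per-probe mixing `U(0.05, 0.95)`. Values are the state
mean (defaults 4 and 9 log2 units, the dynamic range of a normalized
array) plus Gaussian noise (sd 0.7). Two probes map to each universal gene
symbol to exercise probe-to-gene deduplication. Defaults are configuration,
not constants.

What the generator does *not* emulate: platform or batch effects, probe
affinity differences, correlated noise blocks, dropout or the zero
inflation of single-cell counts, and continuous (rather than switch-like)
dependence of marker expression on abundance. Passing tests therefore show
the machinery is correct on data matching the model's assumptions, not that
the method is robust to everything real compendia contain.

One structural consequence is worth stating plainly: on this generator the
three-round expansion recovers *exactly* the planted universal cluster —
nothing weaker attaches. A step threshold on the gene scores of such a
homogeneous list is always strictly above the minimum score, so the
selection step always trims at least one genuine member (probe-level recall
≈ 0.6–0.9 at the default sizes, precision 1.0). On real compendia the
candidate list includes weakly attached probesets and the threshold
separates them from the core — which is precisely the situation the
selection step exists for. The generator keeps the spec'd geometry rather
than planting artificial satellites to flatter the selection metric.

## Problem sizes

The reference synthetic compendium is 1000 samples × 2030 probes (20
universal, 10 subset, 2000 noise), with 100000 random pairs for the null;
the full pipeline runs in about ten seconds. Module tests use a 300-sample,
166-probe version of the same design. Oracle checks run 1000 random step
fits against an exhaustive O(n²) search (n ≤ 200) and 10000 random count
vectors against direct formula evaluation.

## Worked example

```{r, eval = FALSE}
library(beccr)

sim <- generate_compendium(synthetic_config(rng_seed = 1))
cfg <- becc_config("UNI001_at", rng_seed = 2)
res <- run_becc(sim$expr, cfg, sim$annotation)

glance(res)   # set sizes, threshold, Z, p
tidy(res)     # per-probeset table: gs, rank, selected, dynamic range
autoplot(res) # ranked gene scores with the selection threshold
```

## Known limitations

* The BooleanNet statistic's denominator follows the standard sparsity
  z-score form; networks built by other implementations may scale `S`
  differently, so compare relations, not raw statistics, across tools.
* The null's `E[gs]`/`sd(gs)` formulas are exchangeability approximations
  (see above); the Z-test is calibrated only in the sense the original
  procedure defines.
* `S > 50` is unreachable when the informative sample count is below 10000
  (`S <= sqrt(nhat) <= sqrt(total)/2`), so strict-threshold runs on
  desk-scale data legitimately return empty networks; that threshold is
  meant for compendia with tens of thousands of samples.
* No normalization is performed; inputs must already be comparable,
  log2-scale values. `log2p1` is a convenience for count-scale single-cell
  input, not a substitute for proper scaling.
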