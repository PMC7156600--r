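# beccr

Boolean Equivalent Correlated Clusters (BECC) for mining universal
co-expression biomarkers from large log2-scale expression compendia, plus
the validation statistics used to vet candidate markers and a synthetic
compendium generator with planted ground truth.

## The problem and the method

A universal biomarker of a cell type is expressed in every subpopulation of
that type across tissues, so in bulk data its expression tracks the
abundance of the cell type in each sample. Two genuine universal markers are
therefore tightly co-expressed across any sufficiently diverse compendium.
BECC turns that observation into a screen:

1. **Booleanization (StepMiner).** Each probe's sorted values get a rising
   one-step fit; the step midpoint is the threshold, and calls are
   LOW / HIGH outside a ±0.5 log2 noise margin, INTERMEDIATE inside it.
2. **Boolean implications (BooleanNet).** For a probe pair, quadrant counts
   `a00, a01, a10, a11` are tested for sparsity with
   `S = (n̂ − n)/√n̂ > 3` and `p = ½(a_ij/nA_i + a_ij/nB_j) < 0.1`,
   where `n̂` is the independence expectation. Both off-diagonal quadrants
   sparse ⇒ *Boolean equivalent*; one sparse quadrant ⇒ one of four
   asymmetric implications; both diagonal ⇒ *opposite*.
3. **Seed expansion.** Starting from a seed probeset, three rounds of
   equivalence scanning build candidate sets A ⊆ B ⊆ C; the final list L is
   C plus the seed.
4. **Scoring.** Every pair in L gets `score = r² + s²` (Pearson r and a
   symmetrized regression slope, reciprocal taken above 1; both floored at
   0), so scores lie in [0, 2]. Per probe,
   `gs_i = (1/|L|) Σ_k k·score_(k)/2` rank-weights the sorted row of the
   score matrix; a StepMiner fit on the gs values selects the high scorers.
5. **Calibration.** An empirical null from random probe pairs converts
   score moments to `E[gs] = E[score]·(|L|−1)/4` and
   `sd(gs) = √Var[score]·(|L|−1)/4`, and a one-sided Z-test scores the
   selection threshold.

Validation statistics: the high-high co-expression fraction of a gene pair
(midrange or StepMiner thresholds), two-sided variance-ratio F-tests of
marker stability on purified-cell data, and Pearson-correlation ranking
against a reference gene.

## Worked example

```r
library(beccr)

sim <- generate_compendium(synthetic_config(rng_seed = 1))   # 2030 probes x 1000 samples
cfg <- becc_config("UNI001_at", rng_seed = 2)                # S > 3, p < 0.1, 3 steps
res <- run_becc(sim$expr, cfg, sim$annotation)
#> expansion step 1: 19 probes
#> expansion step 2: 19 probes
#> expansion step 3: 19 probes
#> candidates: 20; selected: 12

glance(res)[, c("n_set_a", "n_set_b", "n_set_c", "len_l",
                "gs_threshold", "n_selected", "z", "p_value")]
#> # A tibble: 1 × 8
#>   n_set_a n_set_b n_set_c len_l gs_threshold n_selected     z p_value
#>     <int>   <int>   <int> <int>        <dbl>      <int> <dbl>   <dbl>
#> 1      19      19      19    20         8.24         12  68.2       0

head(tidy(res), 3)
#> # A tibble: 3 × 6
#>   probe_id  gene_symbols    gs  rank selected dynamic_range
#>   <chr>     <chr>        <dbl> <int> <lgl>            <dbl>
#> 1 UNI002_at UGENE01       8.30     1 TRUE              8.93
#> 2 UNI013_at UGENE07       8.28     2 TRUE              8.93
#> 3 UNI019_at UGENE10       8.27     3 TRUE              9.37
```

The expansion finds exactly the 19 probes Boolean-equivalent to the seeded
universal marker (sets B and C add nothing — the planted cluster is
closed), all 20 candidates are planted universal markers, and the step
threshold on the gene scores keeps the tightest-scoring probesets. The
Z-test says a threshold this high is absurdly unlikely under random
pairing. `autoplot(res)` plots the ranked gene scores against the
threshold; `selected_genes(res)` returns the deduplicated gene symbols.

On purified populations:

```r
target <- generate_pure_population(synthetic_config(rng_seed = 1), "target")
high_high_fraction(target$expr, "UNI001_at", "UNI002_at")$fraction_high_high
#> [1] 1
variance_ftest(target$expr["UNI001_at", ], target$expr["SUB001_at", ])$p_value
#> [1] 3.499654e-61
```

A command-line front end over the same functions ships in
`inst/cli/becc.R` (`run`, `booleanize`, `implication`, `eval`, `simulate`
subcommands).

## Package layout

- `R/stepminer.R` — step fits, thresholds, booleanization
- `R/booleannet.R` — quadrant statistics, implication classification, scans
- `R/becc.R` — expansion, scoring, selection, empirical null, `run_becc()`
- `R/evaluate.R` — high-high fraction, variance F-test, correlation ranking
- `R/synthetic.R` — planted-truth compendium generator
- `R/io.R` — TSV / series-matrix / annotation / report readers and writers
- `vignettes/becc-methods.Rmd` — models, assumptions, approximations and
  design choices in detail
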