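# fermkin

Kinetic analysis of **in vitro batch fecal fermentations**, built for
studies that follow the microbial catabolism of dietary polyphenols
(apple procyanidins) and the parallel production of short-chain fatty
acids (SCFAs) over a 48-h incubation.

In such experiments each donor's fecal microbiota is incubated with a
food matrix and sampled on a fixed grid (0, 2, 4, 6, 8, 10, 24, 30,
48 h); a blank fermenter (microbiota alone) runs alongside to measure the
metabolites the inoculum produces by itself. The questions are
quantitative: how fast is each metabolite produced or degraded, how much
substrate is gone after 48 h, and do those rates differ between donors
and between matrices?

## What it computes

Every background-corrected series is summarised by the first-order
**fractional conversion model**

    C(t) = C∞ + (C0 − C∞)·exp(−K·t)

with `C0` the initial concentration (mM), `C∞` the asymptote, and `K`
(h⁻¹) the rate constant — one form for both production (`C∞ > C0`) and
degradation (`C∞ < C0`). Around that core:

* `subtract_background()` — pointwise blank-fermenter correction with
  zero-clipping (clipped indices are recorded, never silent);
* `fit_fractional_conversion()` — deterministic nonlinear least squares
  (profile on `K` + Levenberg–Marquardt polish), returning a model object
  with `print`, `summary`, `coef`, `predict`, `residuals`, `plot` and
  `simulate` methods;
* `degradation_extent()` — observed 48-h extent, `100·(C(0)−C(48))/C(0)`;
* `build_rate_table()` / `run_pipeline()` — per-arm rate and extent
  tables plus per-analyte statistics;
* `pooled_sd()` and `two_way_anova()` — df-weighted pooled standard
  deviation and a from-first-principles two-way (donor, matrix)
  fixed-effects ANOVA with Type II sums of squares;
* `degree_of_methylation()` / `phenolic_class_shares()` — pectin and
  phenolic composition arithmetic for the fermented matrices;
* `build_default_network()`, `simulate_network()`, `generate_study()` —
  a generative model of the proposed procyanidin catabolic network
  (linear first-order reaction system solved exactly by matrix
  exponential), used to produce fully synthetic studies with known
  parameters.

## Worked example

Fit a noiseless acetate production curve generated on the 9-point grid:

```r
library(fermkin)
t9 <- c(0, 2, 4, 6, 8, 10, 24, 30, 48)
fit <- fit_fractional_conversion(t9, fractional_conversion(0, 60, 0.131, t9))
fit
#> Fractional conversion fit (first-order)
#>   C0 = -1.19e-09 mM, Cinf = 60 mM, K = 0.131 /h  [production]
#>   n = 9, RSS = 1.884e-18
```

Run the full pipeline on a simulated study (4 donors × 3 matrices ×
3 replicates plus control arms):

```r
res <- run_pipeline(pipeline_config(seed = 42, out_dir = "out"))
head(res$rate_table[order(res$rate_table$donor), ], 4)
#>   donor matrix      analyte K_per_h extent_48h_pct converged
#> 1    O1   Mcov      acetate   0.159             NA      TRUE
#> 2    O1   Mcov     butyrate   0.158             NA      TRUE
#> 3    O1   Mcov procyanidins   0.131           99.2      TRUE
#> 4    O1   Mcov   propionate   0.162             NA      TRUE
```

Each row is one (donor, matrix, analyte) arm: `K_per_h` is the rate
constant averaged over replicates, and `extent_48h_pct` is the observed
48-h degradation extent (reported only for degraded analytes —
procyanidins here; it is meaningless for products that start at zero).
The simulated contrast is visible directly: acetate production averaged
over donors runs at 0.156 / 0.153 / 0.079 h⁻¹ for Mcov / Mnc / Mno — the
no-linkage matrix ferments at half rate, and the per-analyte ANOVA in
`res$anova_rates$acetate` marks both donor and matrix effects `***`.

Composition arithmetic from the bundled matrix table:

```r
comp <- read_composition(system.file("extdata", "matrix_composition.csv",
                                     package = "fermkin"))
round(degree_of_methylation(comp$Mno$methanol, comp$Mno$cellwall[["GalA"]]))
#> [1] 81
round(phenolic_class_shares(comp$Mno)[["hydroxycinnamic acids"]])
#> [1] 18
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/fermkin-cli.R`
(`Rscript fermkin-cli.R simulate|fit|anova|composition ...`).

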