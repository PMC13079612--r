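# domkit

Dominance-aware genomic prediction for factorial hybrid breeding
populations.

Hybrid performance depends not only on additive gene action but on
dominance — the deviation of heterozygotes from the homozygote midpoint.
`domkit` is a simulation and benchmarking toolkit for studying how much of
that dominance signal different genomic prediction models can use. It is
aimed at quantitative geneticists and breeding-methods researchers who
want a controlled test bed: simulate a hybrid breeding scheme with a known
dominance architecture, run classical and machine-learning predictors on
it, and measure what each one recovers.

## The models

For a biallelic locus coded 0/1/2 (A1A1 / A1A2 / A2A2), the locus-specific
**degree of dominance** is estimated from training-set genotype-class means
of the corrected phenotype,

d = 2 (x̄_A1A2 − x̄_A1A1) / (x̄_A2A2 − x̄_A1A1),

so d = 1 is additive, d = 2 complete dominance of the A2 allele, d = 0
complete recessivity, values outside [0, 2] overdominance (kept, flagged).
Replacing every heterozygote code by its locus's d gives the *transformed*
marker matrix. Five predictors share this machinery:

| model | input | predictor |
|---|---|---|
| AM | dosages | GBLUP, additive kernel G (VanRaden) |
| ADM | dosages | GBLUP, additive + dominance kernels (G, D) |
| CADM | transformed matrix | GBLUP, single combined kernel |
| ML | dosages | XGBoost, Bayesian-tuned |
| ML_Transformed | transformed matrix | XGBoost, Bayesian-tuned |

Variance components come from EMMA-style restricted maximum likelihood
(`gblup()`), with the usual summaries h² = Va/Vp, H² = (Va+Vd)/Vp,
PDV = Vd/Vg and d² = Vd/Vp. The simulator (`simulate_population()`)
generates a founder population, samples female and male parents, crosses
them in a full factorial with recombinant gametes, and calibrates
per-locus dominance degrees by bisection so the realized proportion of
dominance variance and broad-sense heritability hit their nominal levels.

## Worked example

```r
library(domkit)

# a small polygenic scenario: 30% dominance variance, H2 = 0.7
sc <- sim_scenario("polygenic", nominal_pdv = 0.3, nominal_H2 = 0.7,
                   n_chr = 5, n_snp_per_chr = 120, n_qtl_per_chr = 12,
                   n_founders = 400, n_female = 50, n_male = 8, seed = 42)
pop <- simulate_population(sc)
pop
#> sim_population (polygenic): 400 hybrids, 600 SNPs, 60 QTLs
#>   realized PDV 0.302, H2 0.684 (nominal 0.30 / 0.70)

# variance components from a two-kernel REML fit
G <- G_vanraden(pop$markers)
D <- D_vitezica(pop$markers)
fit <- gblup(pop$y, list(additive = G, dominance = D))
summary(fit)
#> variance components
#>   Va = 25.28  Vd = 10.67  Ve = 17.01
#>   h2 = 0.4773  H2 = 0.6788  PDV = 0.2968  d2 = 0.2015
#> fixed effects:
#> (Intercept)
#>    10.25193

# cross-validated comparison of the three classical models
folds <- make_folds(length(pop$y), k = 5, repeats = 2, seed = 1)
res <- run_benchmark(pop$y, pop$markers, models = c("AM", "ADM", "CADM"),
                     folds = folds, seed = 1)
summary(res)
#>   trait model    mean_r       sd_r
#> 1 trait   ADM 0.7457314 0.03264159
#> 3 trait  CADM 0.7194846 0.05686273
#> 2 trait    AM 0.5937363 0.07422785
```

The marker-based REML decomposition recovers the simulated architecture
almost exactly (estimated PDV 0.297 and H² 0.679 against the simulator's
realized 0.302 and 0.684), and the cross-validated predictive abilities
show both dominance-aware kernels far ahead of the additive-only model —
the expected pattern when nearly a third of the genetic variance is
dominance.

A thin command-line wrapper is included for shell pipelines:

```sh
Rscript inst/scripts/domkit.R simulate --scenario scenario.yaml --out simdir/
Rscript inst/scripts/domkit.R benchmark --scenario scenario.yaml \
    --models AM,ADM,CADM,ML,ML_Transformed --out results.csv
Rscript inst/scripts/domkit.R compare --in results.csv --out comparison.csv
```

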