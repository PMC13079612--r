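---
title: "Dominance-aware genomic prediction in simulated hybrid breeding populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance-aware genomic prediction in simulated hybrid breeding populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`domkit` studies how dominance gene action affects genomic prediction of
hybrid performance. It provides five prediction models over a common
simulated (or real) hybrid population:

* **AM** — GBLUP with a single additive relationship matrix (VanRaden
  method 1),
* **ADM** — GBLUP with separate additive and dominance kernels (Vitezica
  coding),
* **CADM** — GBLUP with a single *combined* kernel built from the
  dominance-transformed marker matrix,
* **ML** — XGBoost regression on the raw 0/1/2 dosage matrix,
* **ML_Transformed** — XGBoost on the dominance-transformed matrix.

This vignette documents the model, the simulator that generates the study
populations, the numerical choices, and what the test suite does and does
not establish.

## The degree-of-dominance transformation

For a biallelic locus with genotype classes A1A1 (coded 0), A1A2 (coded 1)
and A2A2 (coded 2), let $\bar x_{A_1A_1}, \bar x_{A_1A_2}, \bar x_{A_2A_2}$
be the mean corrected phenotypes of the three classes in the *training*
individuals, $x_{\min} = \min(\bar x_{A_1A_1}, \bar x_{A_2A_2})$ and
$x_{\max}$ the other homozygote mean. The locus-specific degree of
dominance is

$$ d = \frac{2\,(\bar x_{A_1A_2} - x_{\min})}{x_{\max} - x_{\min}}, $$

in its classical orientation-free form. $d = 1$ means the heterozygote
sits at the homozygote midpoint (pure additivity), $d = 2$ complete
dominance, $d = 0$ complete recessivity, and $d$ outside $[0, 2]$
over/under-dominance. The transformed marker matrix replaces every
heterozygote code 1 with the locus's $d$; homozygote codes are untouched.
The transformation is estimated on training rows only — phenotype-derived
quantities must never see held-out individuals — while allele frequencies
for kernel construction use all genotypes (genotypes of selection
candidates are legitimately available before phenotyping).

**Orientation.** The min/max form measures $d$ from the *worse*
homozygote, whichever allele that is. That reads naturally, but it breaks
the property the transformation exists for: if a locus has additive
effect $a$ and heterozygote deviation $\delta |a|$ toward the favourable
allele, the three genotype-class means are collinear in the transformed
code only when the heterozygote is placed along the dosage axis, i.e.
$d = 2(\bar x_{A_1A_2} - \bar x_{A_1A_1}) / (\bar x_{A_2A_2} - \bar
x_{A_1A_1})$, which equals $1 + \delta$ when A2 is favourable and
$1 - \delta$ when A1 is. The min/max form mirrors the placement at
A1-favourable loci, feeding the combined kernel a code that is no longer
collinear with the class means there. The two forms coincide whenever
the A2 homozygote mean is the larger one — which covers every textbook
example. `estimate_dominance()` therefore defaults to
`orient = "signed"` (the code-axis form) and offers `orient = "minmax"`.

Further estimation choices (`estimate_dominance()`):

* $d$ is a ratio whose denominator is the homozygote span. Loci where
  the span is zero *or statistically indistinguishable from zero* —
  below `span_se_mult = 2` standard errors, the SE computed from the
  homozygote class variances — fall back to $d = 1$ (the locus stays
  additive) and are flagged, as do loci where any genotype class has
  fewer than `min_class_n = 2` training observations. Without the
  identifiability rule a handful of near-zero-span loci take $|d|$ in
  the hundreds and their columns dominate the variance of the entire
  transformed matrix;
* overdominant estimates ($d < 0$ or $d > 2$) are kept and flagged,
  never clamped: the model does not represent overdominance explicitly,
  and silently truncating would hide that mismatch;
* the function takes an already-corrected phenotype vector (simulated
  phenotypes centred by the training mean, or BLUEs) and applies no
  fixed-effect correction itself, so pipelines control the correction.

At desk-scale training sizes the per-locus estimates remain noisy — a
few hundred observations per genotype class — and a large minority of
loci hit the identifiability fallback. This is the main reason the
combined kernel's locus-specific weighting cannot be expected to beat
the two-component kernel model (ADM) in the shipped reduced-scale runs,
whereas both dominance-aware kernels clearly beat the additive-only
model; the margin of the locus-specific approach grows with training
size and with locus-to-locus heterogeneity of the dominance degree.

## Relationship matrices

`G_vanraden()` builds $G = ZZ' / (2\sum_j p_j q_j)$ with $Z$ the dosage
matrix centred by twice the sample allele frequency. `D_vitezica()` codes
dosages 0/1/2 as $-2p^2,\ 2pq,\ -2q^2$ (zero-mean under Hardy–Weinberg
proportions, hence orthogonal to the additive coding) and scales by
$\sum_j (2 p_j q_j)^2$. `K_combined()` applies the VanRaden construction to
the *transformed* matrix: column-mean centering and the constant
$2\sum_j \tilde p_j(1 - \tilde p_j)$ with $\tilde p_j$ half the transformed
column mean. Running the combined kernel through the same code path as the
additive kernel makes the reduction exact: with $d \equiv 1$ the two
kernels agree element-wise to machine precision, and GBLUP predictions
from them coincide. Two alternative scalings (sum of empirical column
variances; $2\sum pq$ of the raw matrix) are available behind the
`scaling` argument; all scalings differ only by a scalar factor, which a
single-kernel GBLUP absorbs into its variance component, so held-out
predictions are unaffected by the choice.

Monomorphic/zero-variance columns are dropped from numerator and
denominator; missing dosages are column-mean imputed (most-frequent class
for the dominance coding) with the imputation rate recorded.

## Kernel REML and GBLUP

`gblup()` fits $y = X\beta + \sum_k u_k + e$, $u_k \sim N(0, \sigma_k^2
K_k)$, $e \sim N(0, \sigma_e^2 I)$.

* **Single kernel.** The restricted likelihood is profiled over the ratio
  $\delta = \sigma_e^2/\sigma_g^2$ after rotating the data into an
  orthonormal basis of the complement of the fixed-effect space (the
  eigendecomposition route of the EMMA algorithm). Brent's method
  maximises over $\log\delta \in [-10, 10]$ with tolerance $10^{-8}$; an
  optimum within $10^{-4}$ of the bracket is flagged as a boundary
  solution (`converged = FALSE`). The basis is built explicitly by QR
  decomposition of $X$ rather than by eigendecomposing the projected
  kernel alone: with a rank-deficient kernel, zero eigenvalues of $SKS$
  are ambiguous between genuine null kernel directions and the
  fixed-effect null space, and the explicit basis removes that ambiguity.
* **Several kernels.** Average-information REML with EM fallback steps
  whenever the AI update would leave the parameter space; convergence at
  relative change $< 10^{-6}$, at most 500 iterations, variance floor
  $10^{-8}\,\mathrm{var}(y)$.
* **Prediction.** Held-out genetic values are conditional means,
  $\hat g_{\text{test}} = \sum_k \sigma_k^2 K_k[\text{test},\text{train}]
  V^{-1}(y - X\hat\beta)$, equivalent to solving the full mixed-model
  equations with the test records missing (the test suite verifies this
  equivalence to $10^{-8}$ on a small example).

Fixed effects are intercept-only in all genomic fits; the phenotypes (or
BLUEs) carry no further covariates here.

## The breeding-scheme simulator

`simulate_population()` emulates a simple factorial hybrid scheme: a
founder population (default 1000 individuals) is split into a female and a
male pool; 300 females and 8 males (defaults) are sampled and crossed in a
full factorial, giving 2400 hybrids; each hybrid receives one independent
recombinant gamete per parent, with Poisson crossovers (mean = 1 per
chromosome, the 1 Morgan map length) at uniform positions. The default
genome is 10 chromosomes with 3000 SNPs and 300 QTLs each (polygenic) or 3
QTLs each (oligogenic), uniformly spaced; these defaults are the
full-scale study conditions, and reduced sizes used by scripts and tests
are always passed explicitly.

Founder haplotypes are Bernoulli draws at per-locus ancestral frequencies
uniform on $[0.05, 0.95]$, passed through a first-order copying process
(`ld_rho = 0.98`): each haplotype allele copies its left neighbour with
probability 0.98, otherwise draws fresh. This induces strong local
linkage disequilibrium decaying over tens of loci without the cost of a
coalescent simulation. The default is deliberately high: dominance
relationships between individuals are tagged by markers only through the
*fourth* power of marker–QTL LD (heterozygosity concordance), so weak
founder LD leaves dominance variance invisible to SNP kernels even when
additive relationships are tracked well. The criterion behind the default
is mechanistic: the off-diagonal correlation between the SNP-based and
true-QTL-based dominance kernels should approach the additive one; at
weak copying probabilities the dominance concordance collapses and every
dominance-aware model degenerates to its additive counterpart. The high
default emulates the near-perfect nearest-marker LD of a dense panel,
where markers sit fractions of a centimorgan from any QTL. What this does
*not* emulate: realistic long-range LD decay profiles, allele-frequency
spectra shaped by selection, heterotic-group divergence, or
genotype-by-environment structure. Conclusions from passing tests are
therefore about model behaviour under controlled dominance architectures,
not about any particular real population.

### Trait architectures

Genetic values follow the classical biallelic parameterisation

$$ g_i = \mu + \sum_q \left[ a_q (x_{iq} - 1) +
   \delta_q |a_q| \, \mathbb 1\{x_{iq} = 1\} \right], $$

with additive effects $a_q \sim N(0,1)$ and locus-specific dominance
degrees $\delta_q = \mu_\delta + 0.2\, z_q$, $z_q \sim N(0,1)$ held fixed
while $\mu_\delta$ is calibrated. The $|a_q|$ directs dominance toward the
favourable allele; the 0.2 spread expresses that the degree of dominance
varies from locus to locus.

Calibration (`build_architecture()`): $\mu_\delta$ is found by bisection
(tolerance 0.01 on PDV, at most 40 iterations) so that the *realized*
proportion of dominance variance — from `realized_components()`, which
takes the variance of fitted values of the joint least-squares regression
of $g$ on all QTL dosages as $V_a$ and the remainder of $\mathrm{var}(g)$
as $V_d$ — matches the scenario's nominal PDV. The residual variance is
then set from the realized genotypic variance so that
$V_g/(V_g + V_e)$ equals the nominal broad-sense heritability; phenotypes
add i.i.d. normal noise. Because calibration targets the realized
decomposition, realized PDV tracks nominal PDV to within about 0.01 and
realized $H^2$ deviates from nominal only through the sampling variance
of the residual draw (about $H^2(1-H^2)\sqrt{2/n}$, well inside the
$\pm 0.05$ band at $n \ge 600$). A nominal PDV of 0 forces
$\delta_q \equiv 0$ exactly. The dispersion alone ($\mu_\delta = 0$)
already produces a small PDV (about 0.01 at 300 QTLs), so nominal values
below that floor are reported with a flag.

The scenario grid used by the reproduction scripts is 2 architectures
$\times$ 3 heritabilities $\{0.3, 0.6, 0.8\}$ $\times$ 16 nominal
dominance levels evenly spaced on $[0, 0.4]$ (96 scenarios). Within one
architecture the trait scenarios share a genotype population — genotypes
are trait-independent, exactly as one field population is phenotyped for
many traits — with trait-level draws seeded per scenario.

## Boosted-tree models and tuning

`xgb_bayes_tune()` optimises XGBoost hyperparameters by Gaussian-process
Bayesian optimisation of the inner-cross-validated mean squared error: 20
evaluated configurations, 3 inner folds fixed once per tuning run, a
Latin-hypercube design for the first 5 points, then
expected-improvement acquisition under a Matern-5/2 GP (length-scale 0.25
in the unit-normalised space, standardised objective, nugget $10^{-6}$)
maximised over 512 random candidates per iteration. The default space:
trees 100–1000, learning rate 0.01–0.3 (log), depth 2–10, row subsample
0.5–1, column subsample 0.3–1, L2 penalty $10^{-3}$–10 (log). Features
enter as-is: trees are invariant to monotone per-feature transforms, and
the transformation's information lies in where the heterozygote is placed
between the homozygotes.

Everything is deterministic given the seed. Two reproducibility caveats
are deliberate contracts, asserted by the tests: predictions are
bit-identical only for identical input layout and seed, and they are
*not* invariant to consistent column permutation (split-gain ties on
ternary features and index-based column subsampling), although held-out
accuracy is statistically unaffected.

The benchmark harness tunes once per trait by default in the reproduction
scripts (`tune_schedule = "per_trait"`); per-repeat and per-fold schedules
are available. The best configuration is then refitted on each training
fold.

## Trial pipeline

The phenotypic pipeline mirrors multi-environment hybrid trials: (i)
marker QC drops loci with minor-allele frequency strictly below 0.05 or
missingness strictly above 0.2 (a locus at exactly either threshold is
kept); (ii) within each environment (location × year) a fixed-effects
model $y_{ij} = \mu + H_i + R_j + e_{ij}$ is fitted once and records with
$|e_{ij}| > 2\hat\sigma$ are removed in a single pass; (iii) step-1 BLUEs
($\hat\mu + \hat H_i$, sum-to-zero constraints, so on the trait scale) are
computed per environment by default — the per-location-pooling-years
variant sits behind `scope = "location"` — so that (iv) step-2 can fit
hybrid as fixed and environment as random, the environment variance
estimated by the package's own kernel REML with the environment-incidence
cross-product as covariance structure. With two replicates per
environment, a gross error splits between its record and the hybrid's
other records, so single-pass removal can flag a partner record as well;
with more replicates the planted record alone crosses the threshold. This
is a property of the stated single-pass procedure, not a defect.

## Benchmarking and inference

`run_benchmark()` evaluates models under repeated k-fold cross-validation
(5 × 10 at full scale; scripts use 5 × 2 at reduced scale), computing the
Pearson correlation between predictions and observations per fold and
averaging fold-level values (never pooling predictions across folds).
`compare_models()` runs a one-way ANOVA of fold-level r per trait,
adjusts trait-level p-values by Benjamini–Hochberg across traits, and
applies Tukey HSD to traits passing FDR < 0.05.

## Problem sizes in scripts and tests

The full study conditions (2400 hybrids × 30,000 SNPs × 96 scenarios ×
five models × 5×10 CV) are deliberately scaled down in the shipped
scripts; these sizes are the package's own desk-scale choices:

* variance-grid reproduction (`scripts/acceptance.R`): 1200 hybrids
  (150 females × 8 males), 3000 SNPs, 300 (polygenic) / 30 (oligogenic)
  QTLs, the full 3 × 16 grid per architecture;
* cross-validated model comparison: 800 hybrids (100 × 8), 1500 SNPs,
  150 QTLs, two polygenic high-dominance scenarios
  ($H^2, \mathrm{PDV}$) = (0.8, 0.35), (0.6, 0.40), 5-fold × 2 repeats,
  tuning once per trait;
* test suite: the same machinery at 500–800 hybrids with shortened tuning
  (8 iterations), which keeps the ordering properties visible while the
  whole suite stays in the tens of minutes.

At these sizes fold-level predictive abilities carry more sampling noise
than at full scale; the scripts therefore target orderings and
coarse-grained quantities (grid maxima, relative improvements), not
per-scenario point estimates.

## Known limitations

* The combined kernel and the transformation assume dominance acts
  through the heterozygote's position between the homozygote means;
  overdominance is recorded but not modelled.
* The dominance-transformed matrix is trait-specific: one transformation
  (and one combined kernel) per trait and training split.
* The founder model is a frequency-plus-copying process, not a coalescent;
  long-range LD and population structure of real panels are out of scope.
* `realized_components()` attributes LD-induced covariance between
  additive and dominance terms to the additive side (regression-based
  decomposition); with more QTLs than individuals it falls back to a
  per-locus decomposition and flags the output.
* Epistasis and genotype-by-environment interaction are not simulated or
  modelled.
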