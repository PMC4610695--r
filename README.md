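# atemp

Joint association testing of multiple phenotypes against a single genetic
variant, for GWAS-style analyses where several correlated (and possibly
non-normal) traits measure one underlying disorder and per-trait tests waste
power.

## What it computes

For genotype scores $G_i \in \{0,1,2\}$ (minor-allele counts) and phenotype
vectors $\mathbf{Y}_i \in \mathbb{R}^K$ on $n$ unrelated individuals, the core
statistic is the score test of the reversed (proportional-odds) regression of
genotype on phenotypes:

$$
S = \frac{W^\top V^{-1} W}{n(1-\bar\pi_0)(1-\bar\pi_1)(1-\bar\pi_2)},
\qquad W = \sum_i \bar g_i \mathbf{Y}_i,
\qquad V = n^{-1} \sum_i (\mathbf{Y}_i - \bar{\mathbf{Y}})(\mathbf{Y}_i - \bar{\mathbf{Y}})^\top,
$$

with genotype weights $\bar g_i = n^{-1}\sum_j \mathrm{sign}(G_i - G_j)$ and
$\bar\pi_g$ the genotype class proportions; under the null
$S \sim \chi^2_K$. The identical number arises as the standardized
generalized Kendall's tau U-statistic (sign kernel on genotype, identity
kernel on phenotypes) — both routes are implemented
(`multiphen_score()`, `kendall_tau_score()`) and tested against each other.

Because the identity kernel uses the raw phenotype scale, power degrades for
heavy-tailed or skewed phenotypes. Two per-column transformations restore it:

* **ATeMP-rn** — rank-based inverse normal, $\Phi^{-1}(R_i/(n+1))$;
* **ATeMP-or** — ordinal residual, $\sum_j \mathrm{sign}(y_i - y_j)$.

The package also ships the bivariate and high-dimensional phenotype
simulators used to characterize the tests, a Monte-Carlo power/type-I-error
harness over scenario grids (YAML-configurable, with `autoplot()` power
curves), per-SNP testing from VCF or 0/1/2 dosage matrices with covariate
adjustment, Bonferroni correction and permutation p-values, and a small CLI
(`inst/scripts/atemp.R`) with `simulate`, `power` and `test` subcommands.

## Worked example

```r
library(atemp)

# a cohort of 2000 individuals, two correlated phenotypes, one causal variant
# with a skewed (standardized Gamma) shared factor
d <- simulate_bivariate(2000, maf = 0.2, dist = "gamma12",
                        beta_g1 = 0.1, beta_g2 = 0.1, r = 0.4, seed = 1)

atemp_test(d, phenotypes = c(Y1, Y2), genotype = g, method = "multiphen")
#> MultiPhen score test
#>   statistic = 11.4715 on 2 df, p = 0.003228 (n = 2000)

atemp_test(d, phenotypes = c(Y1, Y2), genotype = g, method = "atemp-rn")
#> ATeMP-rn (rank inverse normal) test
#>   statistic = 13.5035 on 2 df, p = 0.001169 (n = 2000)
```

The same variant, tested jointly on the same data: the untransformed score
test gives p ≈ 3.2e-3 while the rank-inverse-normal transform sharpens it to
p ≈ 1.2e-3 — the transform recovers efficiency that the raw scale loses on
skewed phenotypes. `tidy()` and `glance()` return the result as one-row
tibbles; `test_snps()` applies the same pipeline per SNP across a genotype
file:

```r
res <- test_snps("phenotypes.tsv", "genotypes.vcf",
                 covariates = "covariates.tsv", method = "atemp-rn")
```

A type-I-error grid at a fixed significance level:

```r
grid <- run_power_grid(
  scenario_bivariate(500, maf = 0.05, dist = "t3", beta_g1 = 0, beta_g2 = 0, r = 0.5),
  methods = c("multiphen", "atemp-rn"), reps = 10000, alpha = 5e-4, seed = 1,
  quiet = TRUE
)
dplyr::select(as.data.frame(grid), method, rejection_rate, mc_se)
#>      method rejection_rate        mc_se
#> 1  atemp-rn          4e-04 0.0001999600
#> 2 multiphen          1e-03 0.0003160696
```

The transformed test holds the 5e-4 level within Monte-Carlo error while the
untransformed one shows the mild small-sample inflation expected for t(3)
phenotypes; by n = 2000 that inflation is gone.

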