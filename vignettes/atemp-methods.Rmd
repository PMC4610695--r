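---
title: "Methods: multi-phenotype association testing with atemp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-phenotype association testing with atemp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The testing problem

A single biallelic variant with genotype score $G_i \in \{0, 1, 2\}$ (minor-allele
count) is tested for joint association with $K$ phenotypes
$\mathbf{Y}_i = (Y_{i1}, \dots, Y_{iK})^\top$ measured on $n$ unrelated
individuals. Joint testing matters for pleiotropic variants and for bundles of
intermediate phenotypes that measure one underlying trait: a variant with weak
marginal effects on several correlated phenotypes can be invisible to
phenotype-at-a-time GWAS yet clearly associated with the phenotype vector.

The package implements the *reversed regression* approach: rather than
modelling each phenotype given the genotype (which requires committing to a
phenotypic distribution), the genotype is treated as an ordinal response and
the phenotypes as predictors in a proportional-odds model
$$
P(G_i \le g) = \frac{1}{1 + \exp(-\alpha_{0} - \sum_k \alpha_k Y_{ik})}.
$$
The null hypothesis of no association is $\alpha_1 = \dots = \alpha_K = 0$.
The package never fits this likelihood: only its score test is needed, and the
score statistic has a closed form,
$$
S \;=\; \frac{W^\top V^{-1} W}{n\,(1-\bar\pi_0)(1-\bar\pi_1)(1-\bar\pi_2)},
\qquad
W = \sum_{i=1}^n \bar g_i \mathbf{Y}_i,
\qquad
V = \frac{1}{n}\sum_{i=1}^n (\mathbf{Y}_i - \bar{\mathbf{Y}})
                             (\mathbf{Y}_i - \bar{\mathbf{Y}})^\top,
$$
where $\bar\pi_g$ is the sample proportion of genotype class $g$ and
$\bar g_i = n^{-1} \sum_j \operatorname{sign}(G_j - G_i)$ is the centred
genotype weight computed by `genotype_weights()` (equal to $1-\bar\pi_0$,
$\bar\pi_2-\bar\pi_0$ or $\bar\pi_2-1$ for genotype 0, 1, 2; the global sign
convention cancels in the quadratic form). Under the null, $S$ is
asymptotically $\chi^2_K$; `multiphen_score()` returns $S$, $K$ and the upper
tail probability.

### Equivalence with the generalized Kendall's tau

The same statistic arises from a nonparametric direction. The generalized
Kendall's tau U-statistic with the sign kernel for the ordinal genotype and
the identity kernel for the phenotypes is
$$
U = \frac{2}{n(n-1)} \sum_{i>j} \operatorname{sign}(G_i - G_j)
    (\mathbf{Y}_i - \mathbf{Y}_j) \;\propto\; \sum_i \bar g_i \mathbf{Y}_i = W ,
$$
and standardizing $U$ by its estimated variance conditional on the phenotypes
gives
$$
S_2 = W^\top \Bigl[(1-\bar\pi_0)(1-\bar\pi_1)(1-\bar\pi_2)
      \sum_i (\mathbf{Y}_i-\bar{\mathbf{Y}})(\mathbf{Y}_i-\bar{\mathbf{Y}})^\top
      \Bigr]^{-1} W ,
$$
which is algebraically identical to $S$ (the key identity is that the
empirical variance of the weights equals
$(1-\bar\pi_0)(1-\bar\pi_1)(1-\bar\pi_2)$, and $\sum_i \bar g_i = 0$).
`kendall_tau_score()` evaluates this second form directly; the test suite
holds the two routes to within $10^{-10}$ relative difference and checks the
pairwise double sum literally on small instances. The proportionality
constant linking the pairwise form (with kernel
$\operatorname{sign}(G_i - G_j)$ over $i > j$) to $W$ is $-2/(n-1)$; the
sign reflects the orientation of the closed-form weights and is irrelevant
to the statistic.

Because the kernel on the phenotype side is the identity, the statistic uses
the *raw phenotype scale*. That choice is efficient under normality but loses
power when phenotypes are heavy-tailed or skewed — exactly as a mean-based
test loses efficiency relative to rank tests away from normality. The two
transformations below recover it.

## The two phenotype transformations

Both are applied per phenotype column, before testing, by
`apply_transform()` or the `method` argument of `atemp_test()`:

* **ATeMP-rn** (`"atemp-rn"`, `rank_inverse_normal()`): replace each value by
  the normal quantile of its rank, $y^*_i = \Phi^{-1}(R_i/(n+1))$. Ties get
  mid-ranks. The transformed column is near-normal regardless of the input
  distribution.
* **ATeMP-or** (`"atemp-or"`, `ordinal_residual()`): replace each value by its
  pairwise sign sum $y^*_i = \sum_j \operatorname{sign}(y_i - y_j)$, the
  residual of an ordinal (proportional-odds) model for the phenotype — the
  natural choice when a phenotype is itself ordinal, or as a sign-kernel
  variant for continuous data. The implementation uses the exact identity
  $\sum_j \operatorname{sign}(y_i - y_j) = 2\,\tilde R_i - (n+1)$ with
  mid-ranks $\tilde R_i$, which holds including ties; the brute-force pairwise
  sum is kept as a test oracle.

Both are rank statistics: any strictly monotone distortion of a phenotype
leaves the resulting test statistic unchanged. On tie-free data the two
transforms induce the same ranks but different spacings ($\Phi^{-1}$ is
nonlinear), so they give different — usually close — statistics. Degrees of
freedom are always $K$, transformed or not.

`method` may also be a vector with one entry per phenotype, so that only a
skewed phenotype is transformed while well-behaved ones enter untouched; the
simulation harness always applies one method uniformly, which is how the
power experiments are defined.

### Covariates, missing data, and numerical points

* Covariates (e.g. age, sex) are removed by least-squares residualization of
  each phenotype *before* any transformation — transforming first and
  residualizing after would destroy the rank-invariance rationale. The
  genotype side cannot be adjusted in this formulation, since the test
  conditions on the phenotypes. Degrees of freedom stay $K$.
* Individuals with a missing genotype or any missing phenotype/covariate are
  dropped listwise, per variant; `n_used` is reported.
* $V$ is never inverted explicitly: the quadratic form is computed through a
  Cholesky solve. A singular $V$ (constant or collinear phenotype columns)
  is an error asking for collinearity removal; a condition number above
  $10^{10}$ triggers a warning.
* Two observed genotype classes are allowed (the absent class has
  $\bar\pi = 0$ and the formulas remain valid); one class is an error, and
  the per-SNP driver `test_snps()` skips such variants with a warning.
* $\operatorname{sign}(0) = 0$ throughout: tied genotype or phenotype pairs
  contribute nothing.
* The permutation option permutes genotype labels, which leaves both
  $\bar\pi$ and $V$ unchanged; only $W$ is recomputed per permutation, making
  the permutation p-value $(1 + \#\{S_b \ge S_{obs}\})/(1 + B)$ cheap. It is
  reproducible given a seed, and its smallest attainable value is $1/(1+B)$.

## The simulators

The package generates its own evaluation data; no external data are needed.
Two generators define the study conditions, and their defaults *are* those
conditions.

**Bivariate model** (`simulate_bivariate()`):
$$
Y_{1} = \beta_{G1} G + \beta_{E1} E, \qquad
Y_{2} = \beta_{G2} G + \beta_{E2} E + \epsilon,
$$
with $G \sim \mathrm{Binomial}(2, \mathrm{MAF})$ (Hardy–Weinberg), a shared
factor $E$ drawn from one of four standardized error distributions, and
$\epsilon \sim N(0, \sigma^2)$. Given $\beta_{G1}, \beta_{G2}$ and a target
correlation $r$, the remaining coefficients are solved in closed form
(`bivariate_coefficients()`) so that both phenotypes have variance exactly 1
and correlation exactly $r$; infeasible combinations (which would need
$\sigma^2 < 0$) are an error. Defaults: $\beta_{G1} = 0.1$, MAF 0.2 for power
runs; the null uses $\beta_{G1} = \beta_{G2} = 0$ with MAF 0.05.

**High-dimensional model** (`simulate_highdim()`):
$$
Y_k = \beta_k G + \sqrt{a}\, U_k + \sqrt{1-a}\,\varepsilon_k,
\qquad k = 1, \dots, K,
$$
with $(U_1,\dots,U_K)$ multivariate normal with covariance
$\rho_{ij} = 0.8^{|i-j|}$, independent standardized errors $\varepsilon_k$,
and $a = 0.4$, so null phenotypes have unit variance and cross-phenotype
correlation $a\,0.8^{|i-j|}$. The $\sqrt{a}$/$\sqrt{1-a}$ weighting is chosen
so the shared and idiosyncratic components contribute variances $a$ and
$1-a$. The first $\lceil K/3 \rceil$ phenotypes carry
$\beta_k = \sqrt{h^2 / ((1-h^2)\mathrm{Var}(G))}$, which makes the variant
explain exactly the fraction $h^2$ of each affected phenotype's variance;
defaults $h^2 = 0.003$ under normal errors and $0.006$ otherwise, MAF 0.3.
Taking the affected block contiguous (rather than spread out) is a design
choice: adjacent phenotypes are the most correlated under the AR structure,
which is the natural "several measures of one trait" reading of shared
genetic influence; the choice matters little at these effect sizes.

**Error distributions** (`sample_error()`): normal; $t(3)$ (heavy tails);
Laplace with location 1.5 and scale 1 (symmetric, heavier than normal);
Gamma with shape 1 and scale 2 (strong right skew, skewness 2). Every
distribution is centred and scaled to mean 0, variance 1 using its analytic
moments — necessary because the variance-targeting algebra above assumes unit
error variance, which raw Laplace(1.5, 1) or Gamma(1, 2) draws do not have.
The Laplace generator is the difference of two unit exponentials, rescaled.

What the generators deliberately do *not* emulate: related individuals
(twins/families), linkage disequilibrium or multi-variant genotypes,
covariate effects, genotyping error, and ascertainment. Passing results under
these conditions therefore speak to the statistic's behaviour for unrelated
samples with a single clean variant, not to family data.

## The Monte-Carlo harness

`run_power_cell()` simulates `reps` datasets under one scenario, applies one
method, and reports the proportion of asymptotic p-values strictly below
$\alpha$ (the rejection rule is `p < alpha`, matching a fixed significance
level) with its binomial Monte-Carlo standard error.
`run_power_grid()`/`run_grid()` cross scenarios with methods, derive a
deterministic per-cell seed from the grid seed, and return a tibble that
`autoplot()` turns into power curves. Replication defaults follow the study
design: $\alpha = 5\times10^{-4}$, 1000 datasets per power cell, 50\,000 per
type-I cell; the test suite runs the type-I grid at 10\,000 replicates per
cell — rejection-rate estimates then carry a Monte-Carlo standard error of
about $2\times10^{-4}$ at the nominal level, which the assertions account
for — and the acceptance script runs its type-I targets at the full 50\,000.
A dataset whose sampled variant is monomorphic (possible at MAF 0.05 in small
samples, with vanishing probability) is redrawn.

Two behaviours worth knowing about, both visible in the computed grids: the
untransformed statistic shows mild type-I inflation at
$\alpha = 5\times10^{-4}$ for $t(3)$ phenotypes at small $n$ (the asymptotic
$\chi^2$ tail is approached slowly under heavy tails), which disappears by
$n = 2000$ and is absent for the transformed tests; and under heavy-tailed or
skewed errors the transformed tests are clearly more powerful than the
untransformed one, while under normal errors the rank-inverse-normal variant
pays essentially no premium (the ordinal-residual variant pays a small one,
consistent with the classical efficiency of sign-type scores).

## Per-SNP testing on files

`test_snps()` runs the chosen method per SNP across a genotype matrix or a
VCF (GT field, biallelic records), aligning individuals by identifier,
handling per-SNP missingness, skipping monomorphic variants with a warning,
and adding a Bonferroni-adjusted column over the number of SNPs actually
tested (no FDR, by design — the workflow targets small candidate panels).
For VCF input, dosages are oriented so that the *minor* observed allele is
counted, flipping the ALT coding when its frequency exceeds 0.5 (ties stay
on ALT). A thin command-line wrapper with `simulate`, `power` and `test`
subcommands ships in `inst/scripts/atemp.R`.

## Known limitations

* Unrelated individuals only: no variance correction for family or twin
  structure, so cohorts with relatedness need pruning or external adjustment.
* Single-variant tests only; no gene- or set-based aggregation.
* The proportional-odds likelihood is never fitted, so no effect-size
  estimates are produced — the output is a test, not a model fit.
* The asymptotic null requires $n$ reasonably large relative to $K$; for
  small samples (or heavy-tailed untransformed phenotypes) prefer
  `permutations > 0`.
* No automatic rule decides *whether* to transform; choosing between
  `multiphen`, `atemp-rn` and `atemp-or` (globally or per column) is left to
  the analyst, with the rank-inverse-normal variant a safe default for
  continuous non-normal phenotypes and the ordinal-residual variant the
  natural choice for ordinal ones.
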