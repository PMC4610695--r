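# Synthetic phenotype/genotype generators used throughout the power and
# type-I-error studies.

#' Standardized error deviates
#'
#' Draws from one of four error distributions and standardizes to mean 0 and
#' variance 1 using the distribution's analytic moments: `"normal"` is
#' N(0, 1); `"t3"` is Student t with 3 df (variance 3); `"laplace"` is
#' Laplace with location 1.5 and scale 1 (mean 1.5, variance 2); `"gamma12"`
#' is Gamma with shape 1 and scale 2 (mean 2, variance 4). Standardization
#' preserves the shape: t3 keeps its heavy tails, gamma keeps skewness 2.
#'
#' @param n Number of deviates.
#' @param dist One of `"normal"`, `"t3"`, `"laplace"`, `"gamma12"`.
#'
#' @return Numeric vector of length `n` with population mean 0 and variance 1.
#' @export
sample_error <- function(n, dist = c("normal", "t3", "laplace", "gamma12")) {
  dist <- dist[1L]
  switch(dist,
    normal = rnorm(n),
    t3 = rt(n, df = 3) / sqrt(3),
    # Laplace(1.5, 1) as 1.5 + (Exp(1) - Exp(1)); centering removes the
    # location, scaling by sqrt(2) the variance.
    laplace = (rexp(n) - rexp(n)) / sqrt(2),
    gamma12 = (rgamma(n, shape = 1, scale = 2) - 2) / 2,
    abort(paste0("unknown error distribution '", dist, "'"))
  )
}

#' Coefficients for the bivariate phenotype model
#'
#' Solves the moment equations of the bivariate model
#' \eqn{Y_1 = \beta_{G1} G + \beta_{E1} E},
#' \eqn{Y_2 = \beta_{G2} G + \beta_{E2} E + \epsilon}
#' (with standardized shared factor \eqn{E} and
#' \eqn{\epsilon \sim N(0, \sigma^2)}) so that both phenotypes have variance 1
#' and correlation `r`, given \eqn{\mathrm{Var}(G) = 2\,\mathrm{maf}(1-\mathrm{maf})}:
#' \eqn{\beta_{E1} = \sqrt{1 - \beta_{G1}^2 \mathrm{Var}(G)}},
#' \eqn{\beta_{E2} = (r - \beta_{G1}\beta_{G2}\mathrm{Var}(G)) / \beta_{E1}},
#' \eqn{\sigma^2 = 1 - \beta_{G2}^2 \mathrm{Var}(G) - \beta_{E2}^2}.
#'
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param beta_g1,beta_g2 Genetic effects on the two phenotypes.
#' @param r Target correlation between the two phenotypes.
#'
#' @return A one-row tibble with `beta_e1`, `beta_e2`, `sigma2`, `var_g`.
#' @export
#' @examples
#' bivariate_coefficients(maf = 0.2, beta_g1 = 0.1, beta_g2 = 0, r = 0)
bivariate_coefficients <- function(maf, beta_g1 = 0.1, beta_g2 = 0.1, r = 0) {
  if (maf <= 0 || maf > 0.5) abort("`maf` must lie in (0, 0.5]")
  if (abs(r) >= 1) abort("`r` must lie strictly between -1 and 1")
  var_g <- 2 * maf * (1 - maf)
  be1_sq <- 1 - beta_g1^2 * var_g
  if (be1_sq <= 0) {
    abort("infeasible scenario: beta_g1^2 Var(G) exceeds the unit variance of Y1")
  }
  beta_e1 <- sqrt(be1_sq)
  beta_e2 <- (r - beta_g1 * beta_g2 * var_g) / beta_e1
  sigma2 <- 1 - beta_g2^2 * var_g - beta_e2^2
  if (sigma2 < -1e-12) {
    abort(paste0("infeasible scenario: beta_g2^2 Var(G) + beta_e2^2 > 1, so ",
                 "Var(Y2) = 1 cannot be achieved at r = ", r))
  }
  tibble(beta_e1 = beta_e1, beta_e2 = beta_e2,
         sigma2 = max(sigma2, 0), var_g = var_g)
}

#' Simulate a bivariate phenotype cohort
#'
#' Generates `n` unrelated individuals with genotype
#' \eqn{G \sim \mathrm{Binomial}(2, \mathrm{maf})} (Hardy-Weinberg) and two
#' phenotypes from the bivariate model of [bivariate_coefficients()]. The
#' shared factor \eqn{E} follows the chosen error distribution (standardized);
#' both phenotypes have unit variance and correlation `r` by construction.
#' Setting `beta_g1 = beta_g2 = 0` gives null (no-association) data.
#'
#' @param n Number of individuals.
#' @param maf Minor-allele frequency.
#' @param dist Error distribution for the shared factor, see [sample_error()].
#' @param beta_g1,beta_g2 Genetic effect sizes.
#' @param r Target phenotype correlation.
#' @param seed Optional integer seed (identical seeds give identical data).
#'
#' @return A tibble with columns `id`, `g`, `Y1`, `Y2` and a `"scenario"`
#'   attribute recording the parameterization.
#' @export
#' @examples
#' simulate_bivariate(5, seed = 1)
simulate_bivariate <- function(n, maf = 0.2, dist = "normal", beta_g1 = 0.1,
                               beta_g2 = 0.1, r = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- bivariate_coefficients(maf, beta_g1, beta_g2, r)
  g <- rbinom(n, 2L, maf)
  E <- sample_error(n, dist)
  eps <- rnorm(n, sd = sqrt(cf$sigma2))
  out <- tibble(
    id = paste0("id", seq_len(n)),
    g = g,
    Y1 = beta_g1 * g + cf$beta_e1 * E,
    Y2 = beta_g2 * g + cf$beta_e2 * E + eps
  )
  attr(out, "scenario") <- list(
    kind = "bivariate", n = n, K = 2L, maf = maf, dist = dist,
    beta_g1 = beta_g1, beta_g2 = beta_g2, r = r
  )
  out
}

#' Simulate a high-dimensional phenotype cohort
#'
#' Generates `n` unrelated individuals with genotype
#' \eqn{G \sim \mathrm{Binomial}(2, \mathrm{maf})} and `K` phenotypes from the
#' additive factor model
#' \deqn{Y_k = \beta_k G + \sqrt{a}\, U_k + \sqrt{1-a}\,\varepsilon_k,}
#' where \eqn{(U_1,\dots,U_K)} is multivariate normal with AR(1)-type
#' covariance \eqn{\rho_{ij} = 0.8^{|i-j|}} and the \eqn{\varepsilon_k} are
#' independent standardized draws from `dist`. The first `n_causal` phenotypes
#' receive \eqn{\beta_k = \sqrt{h2 / ((1-h2)\,\mathrm{Var}(G))}}, so the
#' variant explains the fraction `h2` of each affected phenotype's variance;
#' the rest have \eqn{\beta_k = 0}. `h2 = 0` gives null data.
#'
#' @param n Number of individuals.
#' @param K Number of phenotypes (at least 3, so that one third is defined).
#' @param maf Minor-allele frequency.
#' @param dist Error distribution, see [sample_error()].
#' @param h2 Fraction of phenotypic variance explained by the variant in each
#'   affected phenotype. Defaults to 0.003 for normal errors and 0.006
#'   otherwise.
#' @param a Weight of the shared (correlated) factor, in (0, 1).
#' @param n_causal Number of affected phenotypes; defaults to
#'   \eqn{\lceil K/3 \rceil}.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `id`, `g`, `Y1`, ..., `YK` and a
#'   `"scenario"` attribute.
#' @export
#' @examples
#' simulate_highdim(5, K = 5, seed = 1)
simulate_highdim <- function(n, K, maf = 0.3, dist = "normal",
                             h2 = if (dist == "normal") 0.003 else 0.006,
                             a = 0.4, n_causal = ceiling(K / 3), seed = NULL) {
  if (K < 3L) abort("`K` must be at least 3 (one third of the phenotypes carry the effect)")
  if (a <= 0 || a >= 1) abort("`a` must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  var_g <- 2 * maf * (1 - maf)
  beta <- rep(0, K)
  if (h2 > 0) beta[seq_len(n_causal)] <- sqrt(h2 / ((1 - h2) * var_g))
  L <- chol(0.8^abs(outer(seq_len(K), seq_len(K), "-")))
  g <- rbinom(n, 2L, maf)
  U <- matrix(rnorm(n * K), n, K) %*% L
  eps <- matrix(sample_error(n * K, dist), n, K)
  Y <- tcrossprod(g, beta) + sqrt(a) * U + sqrt(1 - a) * eps
  colnames(Y) <- paste0("Y", seq_len(K))
  out <- bind_cols(tibble(id = paste0("id", seq_len(n)), g = g), as_tibble(Y))
  attr(out, "scenario") <- list(
    kind = "highdim", n = n, K = as.integer(K), maf = maf, dist = dist,
    h2 = h2, a = a, n_causal = as.integer(n_causal)
  )
  out
}
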