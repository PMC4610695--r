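# Core score/Kendall statistics for multi-phenotype association against one
# biallelic variant.

# Validate and align a phenotype matrix against a genotype vector. Returns
# list(Y, g) with complete cases only.
check_inputs <- function(y, g, snp = NULL) {
  Y <- as.matrix(y)
  if (!is.numeric(Y)) abort("phenotypes must be numeric")
  if (is.data.frame(g)) g <- g[[1L]]
  if (nrow(Y) != length(g)) {
    abort("phenotype rows and genotype length differ; align individuals first")
  }
  keep <- complete.cases(Y) & !is.na(g)
  Y <- Y[keep, , drop = FALSE]
  g <- check_genotype(g[keep], snp = snp)
  if (nrow(Y) < ncol(Y) + 2L) {
    abort("too few complete observations for the number of phenotypes")
  }
  list(Y = Y, g = g)
}

# Shared internal machinery: weights, W, the centred phenotype whitened by the
# Cholesky factor of V (reused by the permutation loop), and the statistic.
atemp_core <- function(Y, g) {
  n <- length(g)
  pi0 <- mean(g == 0L)
  pi1 <- mean(g == 1L)
  pi2 <- mean(g == 2L)
  gbar <- c(1 - pi0, pi2 - pi0, pi2 - 1)[g + 1L]
  Yc <- sweep(Y, 2L, colMeans(Y))
  V <- crossprod(Yc) / n
  R <- tryCatch(chol(V), error = function(e) {
    abort(paste0("phenotype covariance matrix is singular; remove constant ",
                 "or collinear phenotype columns before testing"))
  })
  if (kappa(V) > 1e10) {
    warn("phenotype covariance matrix is ill-conditioned (kappa > 1e10); the statistic may be unstable")
  }
  denom <- n * (1 - pi0) * (1 - pi1) * (1 - pi2)
  # W' V^{-1} W = || R^{-T} W ||^2; precompute Yc R^{-1} so a permuted W only
  # costs one crossprod.
  Ystar <- t(backsolve(R, t(Yc), transpose = TRUE))
  w <- crossprod(Ystar, gbar)
  list(
    statistic = sum(w^2) / denom, df = ncol(Y), n = n,
    gbar = gbar, Ystar = Ystar, denom = denom,
    W = crossprod(Yc, gbar), V = V, pis = c(pi0, pi1, pi2)
  )
}

new_atemp_test <- function(statistic, df, n_used, method, n_dropped = 0L,
                           p_permutation = NULL, permutations = NULL,
                           snp = NULL) {
  structure(
    list(
      statistic = statistic,
      df = df,
      p_value = pchisq(statistic, df = df, lower.tail = FALSE),
      p_permutation = p_permutation,
      permutations = permutations,
      method = method,
      n_used = n_used,
      n_dropped = n_dropped,
      snp = snp
    ),
    class = "atemp_test"
  )
}

#' MultiPhen score statistic
#'
#' Score test of association between a single biallelic variant and \eqn{K}
#' phenotypes, derived from the proportional-odds regression of the genotype
#' score on the phenotypes. The statistic is
#' \deqn{S_1 = \frac{W^\top V^{-1} W}{n(1-\bar\pi_0)(1-\bar\pi_1)(1-\bar\pi_2)},}
#' with \eqn{W = \sum_i \bar g_i Y_i} (see [genotype_weights()]) and
#' \eqn{V = n^{-1}\sum_i (Y_i-\bar Y)(Y_i-\bar Y)^\top}. Under no association
#' \eqn{S_1 \sim \chi^2_K}. Only the closed-form score test is computed; the
#' proportional-odds likelihood itself is never fitted.
#'
#' @param y Numeric matrix or data frame of phenotypes (rows are individuals).
#' @param g Genotype vector of minor-allele counts in \{0, 1, 2\}; rows with a
#'   missing genotype or any missing phenotype are dropped listwise.
#' @param permutations If > 0, number of genotype-label permutations used to
#'   add a permutation p-value (see [permutation_pvalue()]).
#' @param seed Optional integer seed making the permutation p-value
#'   reproducible.
#' @param snp Optional variant label carried into results and error messages.
#'
#' @return An object of class `atemp_test` with elements `statistic`, `df`
#'   (= number of phenotypes), `p_value` (upper \eqn{\chi^2_K} tail),
#'   `p_permutation` (if requested), `method`, `n_used` and `n_dropped`.
#'   [tidy()] turns it into a one-row tibble.
#' @seealso [kendall_tau_score()] for the numerically identical
#'   generalized Kendall's tau form; [atemp_test()] for the data-frame
#'   interface with transformations and covariates.
#' @export
#' @examples
#' multiphen_score(matrix(c(1, 2, 3)), c(0, 1, 2)) # statistic = 3
multiphen_score <- function(y, g, permutations = 0, seed = NULL, snp = NULL) {
  n_in <- nrow(as.matrix(y))
  dat <- check_inputs(y, g, snp = snp)
  core <- atemp_core(dat$Y, dat$g)
  res <- new_atemp_test(core$statistic, core$df, core$n,
    method = "multiphen", n_dropped = n_in - core$n, snp = snp
  )
  if (permutations > 0) {
    res$p_permutation <- perm_pvalue_core(core, permutations, seed)
    res$permutations <- as.integer(permutations)
  }
  res
}

#' Generalized Kendall's tau statistic
#'
#' The multi-phenotype generalization of Kendall's rank correlation, with the
#' sign kernel for the (ordinal) genotype and the identity kernel for the
#' phenotypes: the U-statistic is proportional to
#' \eqn{U \propto \sum_i \bar g_i Y_i}, and the test statistic standardizes it
#' by its estimated variance conditional on the phenotypes,
#' \deqn{S_2 = U^\top \widehat{\mathrm{var}}(U \mid Y)^{-1} U
#'   = W^\top \left[(1-\bar\pi_0)(1-\bar\pi_1)(1-\bar\pi_2)
#'     \sum_i (Y_i-\bar Y)(Y_i-\bar Y)^\top\right]^{-1} W.}
#' \eqn{S_2} is algebraically equal to the MultiPhen score statistic
#' \eqn{S_1}; the two entry points differ only in the formula evaluated, which
#' makes the identity a useful cross-check.
#'
#' @inheritParams multiphen_score
#' @return An `atemp_test` object; see [multiphen_score()].
#' @export
#' @examples
#' kendall_tau_score(matrix(c(1, 2, 3)), c(0, 1, 2)) # statistic = 3
kendall_tau_score <- function(y, g, permutations = 0, seed = NULL, snp = NULL) {
  n_in <- nrow(as.matrix(y))
  dat <- check_inputs(y, g, snp = snp)
  Y <- dat$Y
  g <- dat$g
  gbar <- genotype_weights(g, snp = snp)
  W <- crossprod(Y, gbar)
  Yc <- sweep(Y, 2L, colMeans(Y))
  pf <- genotype_freqs(g)
  M <- (1 - pf$pi0) * (1 - pf$pi1) * (1 - pf$pi2) * crossprod(Yc)
  Minv_W <- tryCatch(solve(M, W), error = function(e) {
    abort(paste0("phenotype covariance matrix is singular; remove constant ",
                 "or collinear phenotype columns before testing"))
  })
  res <- new_atemp_test(drop(crossprod(W, Minv_W)), ncol(Y), length(g),
    method = "multiphen", n_dropped = n_in - length(g), snp = snp
  )
  if (permutations > 0) {
    core <- atemp_core(Y, g)
    res$p_permutation <- perm_pvalue_core(core, permutations, seed)
    res$permutations <- as.integer(permutations)
  }
  res
}

perm_pvalue_core <- function(core, B, seed = NULL) {
  B <- as.integer(B)
  if (B < 100L) abort("use at least 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  obs <- core$statistic
  gbar <- core$gbar
  Ystar <- core$Ystar
  denom <- core$denom
  hits <- 0L
  for (b in seq_len(B)) {
    w <- crossprod(Ystar, gbar[sample.int(length(gbar))])
    if (sum(w^2) / denom >= obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + B)
}

#' Permutation p-value for the multi-phenotype score test
#'
#' Permutes the genotype labels `B` times (which leaves the genotype class
#' proportions, and hence the weight values and the phenotype covariance,
#' unchanged), recomputes the statistic for each permutation, and returns
#' \eqn{(1 + \#\{S_{perm} \ge S_{obs}\}) / (1 + B)}.
#'
#' @inheritParams multiphen_score
#' @param B Number of permutations (at least 100).
#' @return An `atemp_test` object with `p_permutation` set.
#' @export
permutation_pvalue <- function(y, g, B = 1000, seed = NULL, snp = NULL) {
  multiphen_score(y, g, permutations = B, seed = seed, snp = snp)
}

# Residualize each phenotype column on covariates (with intercept) by least
# squares. Used before any transformation.
residualize <- function(Y, X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) abort("covariates must be numeric")
  qr.resid(qr(cbind(1, X)), Y)
}

#' Multi-phenotype association test (data-frame interface)
#'
#' Tests the joint association between one genetic variant and several
#' phenotypes held as columns of a data frame. Individuals with a missing
#' genotype or any missing phenotype/covariate are dropped listwise; the
#' phenotypes are optionally residualized on covariates, then transformed
#' per column according to `method` (none for `"multiphen"`, rank inverse
#' normal for `"atemp-rn"`, ordinal residual for `"atemp-or"`), and the score
#' statistic is referred to \eqn{\chi^2_K}.
#'
#' @param data A data frame with one row per individual.
#' @param phenotypes Columns holding the phenotypes (tidyselect, e.g.
#'   `c(Y1, Y2)` or `starts_with("Y")`).
#' @param genotype Column holding minor-allele counts in \{0, 1, 2\}.
#' @param method Test method: `"multiphen"`, `"atemp-rn"` or `"atemp-or"`,
#'   applied to every phenotype; or a vector with one method per phenotype
#'   column to transform only selected phenotypes.
#' @param covariates Optional columns to residualize the phenotypes on
#'   (tidyselect); residualization happens before any transformation.
#' @param permutations If > 0, number of permutations for a permutation
#'   p-value.
#' @param seed Optional integer seed for the permutation p-value.
#' @param snp Optional variant label.
#'
#' @return An `atemp_test` object; use [tidy()] or [glance()] for a tibble.
#' @export
#' @examples
#' d <- simulate_bivariate(500, beta_g2 = 0.1, r = 0.4, seed = 1)
#' atemp_test(d, phenotypes = c(Y1, Y2), genotype = g, method = "atemp-rn")
atemp_test <- function(data, phenotypes, genotype,
                       method = c("multiphen", "atemp-rn", "atemp-or"),
                       covariates = NULL, permutations = 0, seed = NULL,
                       snp = NULL) {
  if (identical(method, c("multiphen", "atemp-rn", "atemp-or"))) {
    method <- "multiphen"
  }
  method <- vapply(method, match_method, character(1), USE.NAMES = FALSE)
  data <- as_tibble(data)
  Y <- as.matrix(select(data, {{ phenotypes }}))
  gcol <- select(data, {{ genotype }})
  if (ncol(gcol) != 1L) abort("`genotype` must select exactly one column")
  g <- gcol[[1L]]
  X <- select(data, {{ covariates }})
  keep <- complete.cases(Y) & !is.na(g)
  if (ncol(X) > 0L) keep <- keep & complete.cases(X)
  n_in <- nrow(Y)
  Y <- Y[keep, , drop = FALSE]
  g <- g[keep]
  if (ncol(X) > 0L) {
    Y <- residualize(Y, as.matrix(X)[keep, , drop = FALSE])
  }
  Y <- apply_transform(Y, method)
  res <- multiphen_score(Y, g, permutations = permutations, seed = seed,
                         snp = snp)
  res$method <- paste(method, collapse = ",")
  res$n_dropped <- n_in - res$n_used
  res
}

#' @export
print.atemp_test <- function(x, ...) {
  lab <- c(multiphen = "MultiPhen score test",
           "atemp-rn" = "ATeMP-rn (rank inverse normal) test",
           "atemp-or" = "ATeMP-or (ordinal residual) test")[x$method]
  if (is.na(lab)) lab <- paste0("multi-phenotype score test (", x$method, ")")
  cat(lab, if (!is.null(x$snp)) paste0(" [", x$snp, "]"), "\n", sep = "")
  cat(sprintf("  statistic = %.4f on %d df, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n_used))
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_permutation, x$permutations))
  }
  if (x$n_dropped > 0) {
    cat(sprintf("  %d individuals dropped for missingness\n", x$n_dropped))
  }
  invisible(x)
}
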