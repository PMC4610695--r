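test_that("hand-derived univariate example gives statistic 3 by both routes", {
  y <- matrix(c(1, 2, 3))
  g <- c(0, 1, 2)
  s1 <- multiphen_score(y, g)
  s2 <- kendall_tau_score(y, g)
  expect_equal(s1$statistic, 3)
  expect_equal(s2$statistic, 3)
  expect_equal(s1$df, 1)
  expect_equal(s1$p_value, pchisq(3, 1, lower.tail = FALSE))
})

test_that("score and Kendall forms agree on random instances", {
  set.seed(21)
  for (i in 1:100) {
    K <- sample(c(1, 2, 5), 1)
    inst <- random_instance(sample(10:200, 1), K, heavy = i %% 2 == 0)
    a <- multiphen_score(inst$Y, inst$g)$statistic
    b <- kendall_tau_score(inst$Y, inst$g)$statistic
    expect_lt(abs(a - b) / max(a, 1), 1e-10)
  }
})

test_that("statistic is invariant to location shifts and positive rescaling", {
  set.seed(22)
  inst <- random_instance(80, 3)
  s0 <- multiphen_score(inst$Y, inst$g)$statistic
  Y_shift <- sweep(inst$Y, 2, c(10, -3, 0.5), "+")
  Y_scale <- sweep(inst$Y, 2, c(2, 0.1, 7), "*")
  expect_equal(multiphen_score(Y_shift, inst$g)$statistic, s0)
  expect_equal(multiphen_score(Y_scale, inst$g)$statistic, s0)
})

test_that("null statistics follow chi-square with df = K", {
  set.seed(23)
  reps <- 5000
  stats <- numeric(reps)
  for (i in seq_len(reps)) {
    inst <- random_instance(150, 2)
    stats[i] <- multiphen_score(inst$Y, inst$g)$statistic
  }
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 2))
  expect_gt(ks$p.value, 0.01)
  # rejection rate at 5% within a binomial 99% band
  rej <- mean(pchisq(stats, 2, lower.tail = FALSE) < 0.05)
  expect_lt(abs(rej - 0.05), 2.58 * sqrt(0.05 * 0.95 / reps))
})

test_that("degenerate phenotype input raises the collinearity error", {
  g <- c(0, 0, 1, 1, 2, 2)
  Y_const <- cbind(rnorm(6), rep(1, 6))
  expect_error(multiphen_score(Y_const, g), "singular")
  Y_coll <- cbind(1:6, 2 * (1:6))
  expect_error(multiphen_score(Y_coll, g), "singular")
  expect_error(kendall_tau_score(Y_coll, g), "singular")
})

test_that("missing genotypes or phenotypes are dropped listwise", {
  set.seed(24)
  inst <- random_instance(60, 2)
  Y <- inst$Y
  g <- inst$g
  Y[3, 1] <- NA
  g[10] <- NA
  res <- multiphen_score(Y, g)
  expect_equal(res$n_used, 58)
  expect_equal(res$n_dropped, 2)
  ref <- multiphen_score(Y[-c(3, 10), ], g[-c(3, 10)])
  expect_equal(res$statistic, ref$statistic)
})

test_that("covariate residualization removes a confounding covariate effect", {
  set.seed(25)
  n <- 300
  inst <- random_instance(n, 2)
  x <- rnorm(n)
  d <- tibble::tibble(
    g = inst$g,
    Y1 = inst$Y[, 1] + 2 * x,
    Y2 = inst$Y[, 2] - x,
    age = x
  )
  adj <- atemp_test(d, c(Y1, Y2), g, covariates = age)
  ref <- multiphen_score(atemp:::residualize(cbind(d$Y1, d$Y2), cbind(x)), d$g)
  expect_equal(adj$statistic, ref$statistic)
  expect_equal(adj$df, 2)
})

test_that("permutation p-values are deterministic, valid and uniform under the null", {
  set.seed(26)
  inst <- random_instance(100, 2)
  a <- multiphen_score(inst$Y, inst$g, permutations = 300, seed = 9)
  b <- multiphen_score(inst$Y, inst$g, permutations = 300, seed = 9)
  expect_equal(a$p_permutation, b$p_permutation)
  expect_error(multiphen_score(inst$Y, inst$g, permutations = 50), "100")

  # an overwhelming effect beats every permutation: p = 1/(1+B)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  while (length(unique(g)) < 2) g <- rbinom(n, 2, 0.3)
  Y <- cbind(g + rnorm(n, sd = 0.05))
  strong <- multiphen_score(Y, g, permutations = 200, seed = 1)
  expect_equal(strong$p_permutation, 1 / 201)

  # null permutation p-values have mean about 1/2 across datasets
  B <- 199
  pvals <- replicate(60, {
    inst <- random_instance(40, 1)
    multiphen_score(inst$Y, inst$g, permutations = B)$p_permutation
  })
  se <- sqrt(1 / 12 / length(pvals))
  expect_lt(abs(mean(pvals) - 0.5), 3 * se + 1 / (1 + B))
})

test_that("permutation and asymptotic p-values agree for moderate samples", {
  set.seed(27)
  n_data <- 200
  p_asym <- numeric(n_data)
  p_perm <- numeric(n_data)
  for (i in seq_len(n_data)) {
    inst <- random_instance(500, 2)
    res <- multiphen_score(inst$Y, inst$g, permutations = 2000)
    p_asym[i] <- res$p_value
    p_perm[i] <- res$p_permutation
  }
  expect_gt(cor(p_asym, p_perm, method = "spearman"), 0.99)
})

test_that("tidy and glance return well-formed one-row tibbles", {
  d <- simulate_bivariate(200, seed = 5)
  res <- atemp_test(d, c(Y1, Y2), g, method = "atemp-or", snp = "rs1")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("snp", "method", "statistic", "df", "p.value", "n"))
  expect_equal(td$method, "atemp-or")
  gl <- glance(res)
  expect_named(gl, c("statistic", "df", "p.value", "n_used", "n_dropped", "method"))
  expect_output(print(res), "ATeMP-or")
})
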