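test_that("rank inverse normal matches the normal-quantile oracle", {
  expect_equal(rank_inverse_normal(c(1, 2, 3)),
               qnorm(c(0.25, 0.5, 0.75)))
  expect_equal(rank_inverse_normal(c(1, 2, 3))[2], 0)

  set.seed(31)
  x <- rnorm(101)
  out <- rank_inverse_normal(x)
  expect_equal(out[which(rank(x) == 51)], 0) # median of odd tie-free column
  expect_equal(sort(out), qnorm(seq_len(101) / 102))
  # symmetric about zero without ties
  expect_equal(sum(out), 0, tolerance = 1e-12)
  # any strictly increasing input maps to the same output as 1..n
  expect_equal(rank_inverse_normal(exp(seq(-2, 5, length.out = 20))),
               rank_inverse_normal(1:20))
})

test_that("rank inverse normal uses mid-ranks for ties and rejects constants", {
  x <- c(1, 2, 2, 3)
  expect_equal(rank_inverse_normal(x),
               qnorm(c(1, 2.5, 2.5, 4) / 5))
  expect_error(rank_inverse_normal(rep(2, 5)), "constant")
  expect_error(rank_inverse_normal(3), "at least two")
})

test_that("ordinal residual equals the brute-force pairwise sign sum", {
  expect_equal(ordinal_residual(c(1, 2, 3)), c(-2, 0, 2))
  expect_equal(ordinal_residual(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(ordinal_residual(c(3, 1, 2, 2)), c(3, -3, 0, 0))

  set.seed(32)
  for (i in 1:60) {
    n <- sample(2:30, 1)
    # discrete support forces ties
    x <- sample(1:5, n, replace = TRUE) + if (i %% 2) 0 else rnorm(n)
    out <- ordinal_residual(x)
    expect_equal(out, brute_sign_sum(x))
    expect_equal(sum(out), 0)
  }
})

test_that("ordinal residual is 2*rank - (n+1) on tie-free data", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    expect_equal(ordinal_residual(x), 2 * rank(x) - (n + 1))
    expect_setequal(ordinal_residual(x), seq(-(n - 1), n - 1, by = 2))
  }
})

test_that("apply_transform dispatches per column and preserves container type", {
  d <- data.frame(a = c(3, 1, 2), b = c(10, 30, 20))
  expect_identical(apply_transform(d, "multiphen"), d)
  or <- apply_transform(d, "atemp-or")
  expect_s3_class(or, "data.frame")
  expect_equal(or$a, c(2, -2, 0))
  m <- as.matrix(d)
  rn <- apply_transform(m, "atemp-rn")
  expect_true(is.matrix(rn))
  expect_equal(rn[, "b"], qnorm(c(1, 3, 2) / 4))
  expect_error(apply_transform(d, "spearman"), "unknown method")
  expect_error(apply_transform(1:5, "multiphen"), "matrix or data frame")
})

test_that("per-column method vectors transform only the selected phenotypes", {
  d <- data.frame(a = c(3, 1, 2), b = c(10, 30, 20))
  mixed <- apply_transform(d, c("multiphen", "atemp-or"))
  expect_equal(mixed$a, d$a)
  expect_equal(mixed$b, ordinal_residual(d$b))
  m <- apply_transform(as.matrix(d), c("atemp-rn", "multiphen"))
  expect_equal(m[, "a"], rank_inverse_normal(d$a), ignore_attr = TRUE)
  expect_equal(m[, "b"], d$b, ignore_attr = TRUE)
  expect_error(apply_transform(d, c("multiphen", "atemp-or", "atemp-rn")),
               "one entry per phenotype")
  set.seed(36)
  dd <- tibble::tibble(g = rbinom(50, 2, 0.3), Y1 = rnorm(50), Y2 = rexp(50))
  res <- atemp_test(dd, c(Y1, Y2), g, method = c("multiphen", "atemp-or"))
  expect_equal(res$method, "multiphen,atemp-or")
  ref <- multiphen_score(cbind(dd$Y1, ordinal_residual(dd$Y2)), dd$g)
  expect_equal(res$statistic, ref$statistic)
})

test_that("transforms are rank statistics: invariant under monotone distortion", {
  set.seed(34)
  inst <- random_instance(120, 2, heavy = TRUE)
  Y <- inst$Y
  Y_distort <- cbind(exp(Y[, 1]), atan(Y[, 2]) * 5 + 1)
  for (m in c("atemp-rn", "atemp-or")) {
    s_raw <- multiphen_score(apply_transform(Y, m), inst$g)$statistic
    s_dis <- multiphen_score(apply_transform(Y_distort, m), inst$g)$statistic
    expect_equal(s_raw, s_dis, tolerance = 1e-10)
  }
  # the untransformed statistic is not invariant (sanity contrast)
  expect_false(isTRUE(all.equal(
    multiphen_score(Y, inst$g)$statistic,
    multiphen_score(Y_distort, inst$g)$statistic
  )))
})

test_that("rank-normal transform is idempotent and distinct from ordinal residuals", {
  set.seed(35)
  x <- rnorm(40)
  once <- rank_inverse_normal(x)
  expect_equal(rank_inverse_normal(once), once, tolerance = 1e-12)
  # the two transforms induce the same ranks but different statistics in K > 1
  inst <- random_instance(80, 2, heavy = TRUE)
  expect_equal(rank(rank_inverse_normal(inst$Y[, 1])),
               rank(ordinal_residual(inst$Y[, 1])))
  s_rn <- multiphen_score(apply_transform(inst$Y, "atemp-rn"), inst$g)$statistic
  s_or <- multiphen_score(apply_transform(inst$Y, "atemp-or"), inst$g)$statistic
  expect_false(isTRUE(all.equal(s_rn, s_or)))
})
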