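# Independent brute-force oracles and random-instance generators shared
# across the test files. These deliberately evaluate the definitions
# literally (pairwise double sums) rather than reusing package internals.

# Pairwise U-statistic with sign kernel for the genotype and identity kernel
# for the phenotypes, evaluated literally over all i > j pairs.
brute_pairwise_U <- function(Y, g) {
  Y <- as.matrix(Y)
  n <- length(g)
  acc <- numeric(ncol(Y))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      acc <- acc + sign(g[i] - g[j]) * (Y[i, ] - Y[j, ])
    }
  }
  2 / (n * (n - 1)) * acc
}

# Pairwise sign sums for one phenotype column.
brute_sign_sum <- function(x) {
  vapply(x, function(xi) sum(sign(xi - x)), numeric(1))
}

# Genotype weights evaluated literally as n^{-1} sum_j sign(G_j - G_i):
# the pair orientation is fixed by the closed form (class 0 gets a positive
# weight, class 2 a negative one).
brute_weights <- function(g) {
  vapply(g, function(gi) mean(sign(g - gi)), numeric(1))
}

# Random aligned (phenotype matrix, genotype) instance with at least two
# genotype classes present.
random_instance <- function(n, K, maf = 0.3, heavy = FALSE) {
  repeat {
    g <- rbinom(n, 2L, maf)
    if (length(unique(g)) >= 2L) break
  }
  Y <- if (heavy) {
    matrix(rt(n * K, df = 3), n, K)
  } else {
    matrix(rnorm(n * K), n, K)
  }
  list(Y = Y, g = g)
}
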