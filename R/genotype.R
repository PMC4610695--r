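#' Genotype class frequencies
#'
#' Proportions of the three genotype classes (0, 1 and 2 copies of the minor
#' allele) in a genotype vector. Missing values must be removed beforehand.
#'
#' @param g Integer vector of per-individual minor-allele counts, each 0, 1
#'   or 2.
#'
#' @return A one-row tibble with columns `pi0`, `pi1`, `pi2` (summing to 1)
#'   and `n`.
#' @export
#' @examples
#' genotype_freqs(c(0, 0, 1, 2))
genotype_freqs <- function(g) {
  g <- check_genotype(g)
  n <- length(g)
  tibble(
    pi0 = sum(g == 0L) / n,
    pi1 = sum(g == 1L) / n,
    pi2 = sum(g == 2L) / n,
    n = n
  )
}

#' Genotype score weights
#'
#' Per-individual weights obtained by averaging the sign kernel of the
#' genotype score against the whole sample,
#' \eqn{\bar g_i = n^{-1}\sum_j \mathrm{sign}(G_j - G_i)} (the pair
#' orientation that matches the closed form below; the overall sign cancels
#' in the test statistic). In terms of the
#' genotype class proportions \eqn{\bar\pi_0, \bar\pi_1, \bar\pi_2} the weight
#' is \eqn{1-\bar\pi_0} for carriers of zero minor alleles,
#' \eqn{\bar\pi_2-\bar\pi_0} for heterozygotes and \eqn{\bar\pi_2-1} for
#' minor-allele homozygotes. The weights always sum to zero, and their
#' empirical variance equals
#' \eqn{(1-\bar\pi_0)(1-\bar\pi_1)(1-\bar\pi_2)}.
#'
#' @inheritParams genotype_freqs
#' @param snp Optional variant label used in error messages.
#'
#' @return Numeric vector of weights, one per individual.
#' @export
#' @examples
#' genotype_weights(c(0, 0, 1, 2)) # 0.5 0.5 -0.25 -0.75
genotype_weights <- function(g, snp = NULL) {
  g <- check_genotype(g, snp = snp)
  pi0 <- mean(g == 0L)
  pi2 <- mean(g == 2L)
  c(1 - pi0, pi2 - pi0, pi2 - 1)[g + 1L]
}

# Validate a genotype vector: integer-valued 0/1/2, no NA, at least two
# distinct classes (a monomorphic variant leaves the statistic undefined).
check_genotype <- function(g, snp = NULL, allow_na = FALSE) {
  if (is.data.frame(g)) g <- g[[1L]]
  if (!is.numeric(g)) {
    abort("genotypes must be numeric minor-allele counts (0, 1 or 2)")
  }
  if (allow_na) g <- g[!is.na(g)]
  if (anyNA(g)) {
    abort("genotype vector contains missing values; align and drop them first")
  }
  if (any(g != round(g)) || any(g < 0) || any(g > 2)) {
    abort("genotypes must be coded as minor-allele counts in {0, 1, 2}")
  }
  g <- as.integer(g)
  if (length(g) < 2L) {
    abort("need at least two individuals with non-missing genotypes")
  }
  if (length(unique(g)) < 2L) {
    lab <- if (is.null(snp)) "the variant" else paste0("variant '", snp, "'")
    abort(paste0(lab, " is monomorphic (a single genotype class); ",
                 "the association statistic is undefined"))
  }
  g
}
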