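#' Rank-based inverse normal transformation
#'
#' Replaces a phenotype column by normal quantiles of its ranks,
#' \eqn{y_i^* = \Phi^{-1}(R_i / (n+1))}, where \eqn{R_i} is the (mid-)rank of
#' \eqn{y_i}. This is the per-column transformation behind the ATeMP-rn test:
#' it is invariant under any strictly monotone distortion of the input and
#' maps heavy-tailed or skewed phenotypes onto a near-normal scale.
#'
#' Ties receive average (mid-)ranks before the quantile map.
#'
#' @param x Numeric vector (one phenotype column), length at least 2.
#'
#' @return Numeric vector of transformed values; symmetric about 0 when there
#'   are no ties.
#' @export
#' @examples
#' rank_inverse_normal(c(1, 2, 3)) # approximately -0.674, 0, 0.674
rank_inverse_normal <- function(x) {
  if (anyNA(x)) abort("missing values in phenotype column; drop them first")
  n <- length(x)
  if (n < 2L) abort("need at least two observations to rank")
  if (max(x) == min(x)) {
    abort("constant phenotype column cannot be rank-transformed")
  }
  qnorm(rank(x, ties.method = "average") / (n + 1))
}

#' Ordinal residual transformation
#'
#' Replaces a phenotype column by its pairwise sign sums,
#' \eqn{y_i^* = \sum_j \mathrm{sign}(y_i - y_j)} with \eqn{\mathrm{sign}(0)=0}.
#' This is the per-column transformation behind the ATeMP-or test; it equals
#' the residual of an ordinal (proportional-odds) model for the phenotype and
#' coincides with \eqn{2 R_i - (n+1)} where \eqn{R_i} is the mid-rank, an
#' identity that holds exactly even with ties. Outputs always sum to zero; a
#' constant column maps to all zeros (and will then fail the downstream
#' covariance-singularity check).
#'
#' @inheritParams rank_inverse_normal
#'
#' @return Numeric vector of sign sums; for tie-free input these are
#'   \eqn{-(n-1), -(n-3), \dots, n-1} in rank order.
#' @export
#' @examples
#' ordinal_residual(c(1, 2, 3))    # -2 0 2
#' ordinal_residual(c(3, 1, 2, 2)) #  3 -3 0 0
ordinal_residual <- function(x) {
  if (anyNA(x)) abort("missing values in phenotype column; drop them first")
  n <- length(x)
  if (n < 2L) abort("need at least two observations")
  # sum_j sign(x_i - x_j) = 2 * midrank_i - (n + 1), exact including ties
  2 * rank(x, ties.method = "average") - (n + 1)
}

#' Apply a phenotype transformation method column-wise
#'
#' Dispatches the per-column phenotype transformation that defines each test
#' method: `"multiphen"` leaves the phenotypes untouched, `"atemp-rn"` applies
#' [rank_inverse_normal()], and `"atemp-or"` applies [ordinal_residual()].
#'
#' @param y Phenotype data: a numeric matrix or data frame with one column per
#'   phenotype.
#' @param method One of `"multiphen"`, `"atemp-rn"`, `"atemp-or"`; either a
#'   single method applied uniformly, or one method per phenotype column for
#'   mixed designs (e.g. transform only the skewed phenotype).
#'
#' @return An object of the same class as `y` (tibbles stay tibbles, matrices
#'   stay matrices) with every column transformed.
#' @export
#' @examples
#' apply_transform(data.frame(a = c(1, 5, 2), b = c(0.1, 0.2, 0.3)), "atemp-or")
apply_transform <- function(y, method = c("multiphen", "atemp-rn", "atemp-or")) {
  if (!is.matrix(y) && !is.data.frame(y)) {
    abort("`y` must be a matrix or data frame of phenotypes")
  }
  if (identical(method, c("multiphen", "atemp-rn", "atemp-or"))) {
    method <- "multiphen"
  }
  fun_of <- function(m) {
    switch(match_method(m),
      "multiphen" = identity,
      "atemp-rn" = rank_inverse_normal,
      "atemp-or" = ordinal_residual
    )
  }
  if (length(method) > 1L) {
    if (length(method) != ncol(y)) {
      abort(paste0("per-column `method` must have one entry per phenotype (",
                   ncol(y), "), got ", length(method)))
    }
    for (k in seq_len(ncol(y))) {
      y[, k] <- fun_of(method[k])(if (is.matrix(y)) y[, k] else y[[k]])
    }
    return(y)
  }
  f <- fun_of(method)
  if (is.matrix(y)) {
    out <- apply(y, 2L, f)
    dimnames(out) <- dimnames(y)
    return(out)
  }
  mutate(y, across(dplyr::everything(), f))
}

match_method <- function(method) {
  choices <- c("multiphen", "atemp-rn", "atemp-or")
  method <- method[1L]
  if (!is.character(method) || !method %in% choices) {
    abort(paste0("unknown method '", paste(method, collapse = ","),
                 "'; must be one of ", paste(choices, collapse = ", ")))
  }
  method
}
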