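#' Tidy an association test result
#'
#' @param x An `atemp_test` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `snp` (if labelled), `method`,
#'   `statistic`, `df`, `p.value`, `p.permutation` (if computed) and `n`.
#' @exportS3Method generics::tidy
#' @export
tidy.atemp_test <- function(x, ...) {
  out <- tibble(
    method = x$method,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value,
    n = x$n_used
  )
  if (!is.null(x$p_permutation)) {
    out <- mutate(out, p.permutation = x$p_permutation, .after = "p.value")
  }
  if (!is.null(x$snp)) out <- mutate(out, snp = x$snp, .before = 1L)
  out
}

#' Glance at an association test result
#'
#' @inheritParams tidy.atemp_test
#' @return A one-row tibble summarising the fit: `statistic`, `df`,
#'   `p.value`, `n_used`, `n_dropped`, `method`.
#' @exportS3Method generics::glance
#' @export
glance.atemp_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value,
    n_used = x$n_used,
    n_dropped = x$n_dropped,
    method = x$method
  )
}
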