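# Monte-Carlo harness: rejection rates over scenario x method grids.

#' Scenario constructors
#'
#' Build one-row scenario tibbles for [run_power_cell()] and
#' [run_power_grid()]. `scenario_bivariate()` parameterizes the two-phenotype
#' shared-factor model (see [simulate_bivariate()]); `scenario_highdim()` the
#' K-phenotype additive factor model (see [simulate_highdim()]).
#'
#' @inheritParams simulate_bivariate
#' @inheritParams simulate_highdim
#' @return A one-row tibble with a common scenario schema (`kind`, `n`, `K`,
#'   `maf`, `dist`, `beta_g1`, `beta_g2`, `r`, `h2`, `a`); fields that do not
#'   apply to the scenario kind are `NA`.
#' @export
#' @examples
#' scenario_bivariate(2000, beta_g2 = 0, r = 0.4)
scenario_bivariate <- function(n, maf = 0.2, dist = "normal", beta_g1 = 0.1,
                               beta_g2 = 0.1, r = 0) {
  bivariate_coefficients(maf, beta_g1, beta_g2, r) # validate feasibility now
  tibble(
    kind = "bivariate", n = as.integer(n), K = 2L, maf = maf, dist = dist,
    beta_g1 = beta_g1, beta_g2 = beta_g2, r = r, h2 = NA_real_, a = NA_real_
  )
}

#' @rdname scenario_bivariate
#' @export
scenario_highdim <- function(n, K, maf = 0.3, dist = "normal",
                             h2 = if (dist == "normal") 0.003 else 0.006,
                             a = 0.4) {
  if (K < 3L) abort("`K` must be at least 3")
  tibble(
    kind = "highdim", n = as.integer(n), K = as.integer(K), maf = maf,
    dist = dist, beta_g1 = NA_real_, beta_g2 = NA_real_, r = NA_real_,
    h2 = h2, a = a
  )
}

# Compile a scenario row into a cheap sampler closure returning list(g, Y).
compile_sampler <- function(sc) {
  n <- sc$n
  if (sc$kind == "bivariate") {
    cf <- bivariate_coefficients(sc$maf, sc$beta_g1, sc$beta_g2, sc$r)
    sd_eps <- sqrt(cf$sigma2)
    function() {
      g <- rbinom(n, 2L, sc$maf)
      E <- sample_error(n, sc$dist)
      list(g = g, Y = cbind(
        sc$beta_g1 * g + cf$beta_e1 * E,
        sc$beta_g2 * g + cf$beta_e2 * E + rnorm(n, sd = sd_eps)
      ))
    }
  } else if (sc$kind == "highdim") {
    K <- sc$K
    var_g <- 2 * sc$maf * (1 - sc$maf)
    beta <- rep(0, K)
    if (sc$h2 > 0) {
      beta[seq_len(ceiling(K / 3))] <- sqrt(sc$h2 / ((1 - sc$h2) * var_g))
    }
    L <- chol(0.8^abs(outer(seq_len(K), seq_len(K), "-")))
    sqa <- sqrt(sc$a)
    sqe <- sqrt(1 - sc$a)
    function() {
      g <- rbinom(n, 2L, sc$maf)
      U <- matrix(rnorm(n * K), n, K) %*% L
      eps <- matrix(sample_error(n * K, sc$dist), n, K)
      list(g = g, Y = tcrossprod(g, beta) + sqa * U + sqe * eps)
    }
  } else {
    abort(paste0("unknown scenario kind '", sc$kind, "'"))
  }
}

# Minimal statistic -> p-value path used inside Monte-Carlo loops.
stat_pvalue <- function(Y, g) {
  n <- length(g)
  pi0 <- mean(g == 0L)
  pi1 <- mean(g == 1L)
  pi2 <- mean(g == 2L)
  gbar <- c(1 - pi0, pi2 - pi0, pi2 - 1)[g + 1L]
  Yc <- sweep(Y, 2L, colMeans(Y))
  W <- crossprod(Yc, gbar)
  V <- crossprod(Yc) / n
  S <- sum(W * solve(V, W)) / (n * (1 - pi0) * (1 - pi1) * (1 - pi2))
  pchisq(S, df = ncol(Y), lower.tail = FALSE)
}

transform_columns <- function(Y, method) {
  if (method == "multiphen") return(Y)
  f <- if (method == "atemp-rn") rank_inverse_normal else ordinal_residual
  for (k in seq_len(ncol(Y))) Y[, k] <- f(Y[, k])
  Y
}

#' Monte-Carlo rejection rate for one scenario and method
#'
#' Simulates `reps` datasets under the scenario, applies the method's
#' phenotype transformation followed by the score test, and reports the
#' proportion of asymptotic p-values strictly below `alpha` together with its
#' Monte-Carlo standard error \eqn{\sqrt{\hat p(1-\hat p)/\mathrm{reps}}}.
#' Under a null scenario (zero genetic effects) this estimates type-I error;
#' otherwise, power. Datasets in which the sampled variant happens to be
#' monomorphic are redrawn.
#'
#' @param scenario A one-row scenario tibble from [scenario_bivariate()] or
#'   [scenario_highdim()].
#' @param method `"multiphen"`, `"atemp-rn"` or `"atemp-or"`. The internal
#'   `"kendall"` route computes the untransformed statistic through the
#'   generalized Kendall's tau formula instead; it exists to cross-check the
#'   equivalence end-to-end.
#' @param reps Number of simulated datasets (at least 50).
#' @param alpha Significance level; rejection rule is `p < alpha` (strict).
#' @param seed Optional integer seed; the cell is deterministic given the
#'   seed.
#'
#' @return A one-row tibble: the scenario columns plus `method`, `reps`,
#'   `alpha`, `rejections`, `rejection_rate`, `mc_se`.
#' @export
#' @examples
#' run_power_cell(scenario_bivariate(300, beta_g1 = 0, beta_g2 = 0, r = 0.5),
#'                "multiphen", reps = 50, alpha = 0.05, seed = 1)
run_power_cell <- function(scenario, method = "multiphen", reps = 1000,
                           alpha = 5e-4, seed = NULL) {
  if (method != "kendall") method <- match_method(method)
  reps <- as.integer(reps)
  if (reps < 50L) abort("use at least 50 replicates per cell")
  if (!is.null(seed)) set.seed(seed)
  sc <- as.list(scenario[1L, ])
  sampler <- compile_sampler(sc)
  rejections <- 0L
  ctx <- paste0(sc$kind, " n=", sc$n, " dist=", sc$dist, " method=", method)
  for (i in seq_len(reps)) {
    d <- sampler()
    while (length(unique(d$g)) < 2L) d <- sampler()
    p <- tryCatch(
      {
        if (method == "kendall") {
          kendall_tau_score(d$Y, d$g)$p_value
        } else {
          stat_pvalue(transform_columns(d$Y, method), d$g)
        }
      },
      error = function(e) {
        abort(paste0("replicate ", i, " of cell [", ctx, "] failed: ",
                     conditionMessage(e)))
      }
    )
    if (p < alpha) rejections <- rejections + 1L
  }
  out <- bind_cols(
    as_tibble(scenario[1L, ]),
    tibble(
      method = method, reps = reps, alpha = alpha, rejections = rejections,
      rejection_rate = rejections / reps,
      mc_se = sqrt(rejections / reps * (1 - rejections / reps) / reps)
    )
  )
  class(out) <- c("atemp_power_grid", class(out))
  out
}

#' Run a grid of power/type-I cells
#'
#' Evaluates every scenario x method combination with [run_power_cell()].
#' Each cell gets its own seed derived deterministically from `seed`, so the
#' whole grid is reproducible and insensitive to evaluation order.
#'
#' @param scenarios A tibble of scenario rows ([scenario_bivariate()] /
#'   [scenario_highdim()] outputs, stacked with [dplyr::bind_rows()]).
#' @param methods Character vector of methods.
#' @inheritParams run_power_cell
#' @param quiet Suppress per-cell progress messages.
#'
#' @return A tibble with one row per cell (class `atemp_power_grid`), ready
#'   for [autoplot()].
#' @export
run_power_grid <- function(scenarios, methods = c("multiphen", "atemp-rn", "atemp-or"),
                           reps = 1000, alpha = 5e-4, seed = NULL,
                           quiet = FALSE) {
  if (length(methods) == 0L) {
    warn("no methods requested; returning an empty grid")
    out <- tibble()
    class(out) <- c("atemp_power_grid", class(out))
    return(out)
  }
  cells <- tidyr::crossing(.row = seq_len(nrow(scenarios)), method = methods)
  cells <- dplyr::arrange(cells, .data$.row, .data$method)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sc <- scenarios[cells$.row[i], ]
    cell_seed <- if (is.null(seed)) NULL else (seed + 104729 * i) %% 2147483647
    if (!quiet) {
      message(sprintf("[%d/%d] %s n=%d dist=%s method=%s (%d reps)",
                      i, nrow(cells), sc$kind, sc$n, sc$dist,
                      cells$method[i], as.integer(reps)))
    }
    res[[i]] <- run_power_cell(sc, cells$method[i], reps = reps,
                               alpha = alpha, seed = cell_seed)
  }
  out <- bind_rows(res)
  class(out) <- c("atemp_power_grid", class(out))
  out
}

#' Read a scenario-grid configuration file
#'
#' Parses a YAML description of a simulation grid. Scalar or vector fields
#' (`n`, `dist`, `maf`, `r`, `beta_g2`, `K`, `h2`, ...) are crossed into one
#' scenario per combination. Required fields: `kind` (`bivariate` or
#' `highdim`), `n`, `dist`, `methods`.
#'
#' @param path Path to a YAML file.
#' @return A list with `scenarios` (tibble), `methods`, `reps`, `alpha`,
#'   `seed`.
#' @export
read_grid_config <- function(path) {
  # YAML 1.1 would turn the keys `n` and `y` into booleans; keep them literal.
  keep_letters <- list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x,
    "bool#no" = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x
  )
  cfg <- yaml::read_yaml(path, handlers = keep_letters)
  req <- c("kind", "n", "dist", "methods")
  for (f in req) {
    if (is.null(cfg[[f]])) abort(paste0("config field `", f, "` is missing"))
  }
  if (!cfg$kind %in% c("bivariate", "highdim")) {
    abort("config field `kind` must be 'bivariate' or 'highdim'")
  }
  bad <- setdiff(cfg$methods, c("multiphen", "atemp-rn", "atemp-or"))
  if (length(bad) > 0) {
    abort(paste0("config field `methods` contains unknown entries: ",
                 paste(bad, collapse = ", ")))
  }
  if (cfg$kind == "bivariate") {
    grid <- expand.grid(
      n = cfg$n, dist = cfg$dist,
      maf = cfg$maf %||% 0.2,
      beta_g1 = cfg$beta_g1 %||% 0.1,
      beta_g2 = cfg$beta_g2 %||% 0.1,
      r = cfg$r %||% 0,
      stringsAsFactors = FALSE
    )
    scenarios <- bind_rows(pmap(grid, scenario_bivariate))
  } else {
    if (is.null(cfg$K)) abort("config field `K` is missing (required for kind: highdim)")
    grid <- expand.grid(
      n = cfg$n, dist = cfg$dist, K = cfg$K,
      maf = cfg$maf %||% 0.3,
      a = cfg$a %||% 0.4,
      stringsAsFactors = FALSE
    )
    if (is.null(cfg$h2)) {
      grid$h2 <- ifelse(grid$dist == "normal", 0.003, 0.006)
    } else if (length(cfg$h2) == 1L) {
      grid$h2 <- cfg$h2
    } else {
      abort("config field `h2` must be a single number (omit it for the per-distribution defaults)")
    }
    scenarios <- bind_rows(pmap(grid, scenario_highdim))
  }
  list(
    scenarios = scenarios,
    methods = cfg$methods,
    reps = cfg$reps %||% 1000,
    alpha = cfg$alpha %||% 5e-4,
    seed = cfg$seed
  )
}

#' Run a grid described by a configuration file
#'
#' @param config Path to a YAML file, or a list as returned by
#'   [read_grid_config()].
#' @inheritParams run_power_grid
#' @return An `atemp_power_grid` tibble.
#' @export
run_grid <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_grid_config(config)
  run_power_grid(config$scenarios,
    methods = config$methods, reps = config$reps,
    alpha = config$alpha, seed = config$seed, quiet = quiet
  )
}

#' Power curves from a grid of results
#'
#' Plots rejection rate against a scenario axis (`r` for bivariate grids with
#' several correlations, otherwise `n`), one colour per method, one facet per
#' error distribution.
#'
#' @param object An `atemp_power_grid` tibble.
#' @param x Optional name of the column to use on the horizontal axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.atemp_power_grid <- function(object, x = NULL, ...) {
  if (nrow(object) == 0L) abort("empty results grid")
  if (is.null(x)) {
    x <- if (all(object$kind == "bivariate") &&
             length(unique(object$r)) > 1L) "r" else "n"
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[x]], y = .data$rejection_rate, colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~dist) +
    ggplot2::labs(x = x, y = "rejection rate", colour = "method") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.atemp_power_grid
#' @param results An `atemp_power_grid` tibble.
#' @export
plot_power_curves <- function(results, x = NULL) {
  autoplot.atemp_power_grid(results, x = x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
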