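#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic p-value (the reported
#' comparisons involve thousands of events); the exact small-sample
#' p-value is available behind a flag.
#'
#' @param x,y Numeric samples, each of at least 5 values.
#' @param exact Use the exact p-value (small samples only).
#' @return A list of class `two_sample_test` with `method`, `statistic`,
#'   `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) < 5 || length(y) < 5)
    stop("both samples must contain at least 5 values")
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  structure(list(method = "two-sample Kolmogorov-Smirnov",
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n_x = length(x), n_y = length(y)),
            class = "two_sample_test")
}

#' Two-sample permutation test for means or medians
#'
#' Two-sided permutation p-value
#' `(1 + #{permuted |delta| >= observed |delta|}) / (n_perm + 1)`.
#' When the total number of distinct group assignments is at most
#' `n_perm`, the null is enumerated exhaustively and the p-value is exact.
#'
#' @param x,y Numeric samples (combined n >= 4).
#' @param statistic `"mean"` or `"median"`.
#' @param n_perm Number of random permutations (or enumeration cap).
#' @return A `two_sample_test` list with `statistic` (observed
#'   difference), `p_value`, `n_permutations`, `exhaustive`.
#' @export
permutation_test <- function(x, y, statistic = c("mean", "median"),
                             n_perm = 10000) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "mean") mean else stats::median
  pooled <- c(x, y)
  if (length(pooled) < 4) stop("combined sample size must be at least 4")
  nx <- length(x)
  obs <- abs(stat_fun(x) - stat_fun(y))
  if (stats::sd(pooled) == 0) {
    return(structure(list(method = paste("permutation test,", statistic),
                          statistic = 0, p_value = 1,
                          n_x = nx, n_y = length(y),
                          n_permutations = 0L, exhaustive = TRUE),
                     class = "two_sample_test"))
  }
  n_total <- choose(length(pooled), nx)
  if (n_total <= n_perm) {
    idx <- utils::combn(length(pooled), nx)
    deltas <- apply(idx, 2, function(i)
      abs(stat_fun(pooled[i]) - stat_fun(pooled[-i])))
    p <- mean(deltas >= obs - 1e-12)      # exact: includes the observed
    n_used <- ncol(idx); exh <- TRUE
  } else {
    deltas <- replicate(n_perm, {
      i <- sample(length(pooled), nx)
      abs(stat_fun(pooled[i]) - stat_fun(pooled[-i]))
    })
    p <- (1 + sum(deltas >= obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm; exh <- FALSE
  }
  structure(list(method = paste("permutation test,", statistic),
                 statistic = stat_fun(x) - stat_fun(y), p_value = p,
                 n_x = nx, n_y = length(y),
                 n_permutations = n_used, exhaustive = exh),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$n_x, x$n_y))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' @param values Numeric sample (n >= 10).
#' @param statistic Function of a numeric vector.
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, statistic = mean, level = 0.95,
                         n_boot = 2000) {
  stopifnot(length(values) >= 10, level > 0, level < 1)
  bs <- replicate(n_boot, statistic(sample(values, replace = TRUE)))
  a <- (1 - level) / 2
  unname(stats::quantile(bs, c(a, 1 - a)))
}
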