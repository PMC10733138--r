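# Inferential toolkit: percentile bootstrap, Spearman t-test, Steiger's Z.
# No multiple-testing adjustment anywhere by design.

#' Percentile bootstrap estimate, CI and two-sided p
#'
#' Resamples `data` (a vector, or the rows/groups of a data frame) with
#' replacement, applies `statistic`, and returns the point estimate, a
#' percentile confidence interval and a two-sided p-value for the null
#' value from the resample distribution. Reproducible under `seed`.
#'
#' @param data A vector or data frame; the resampling unit is an element
#'   (row), or a level of `group` when given (e.g. regions).
#' @param statistic Function of a resample returning one number.
#' @param n_reps Bootstrap replications (default 10000; at least 100
#'   required for a CI).
#' @param ci_level Confidence level (default 0.95).
#' @param null_value Null value for the two-sided p (default 0).
#' @param group Optional grouping vector defining the resampling unit.
#' @param seed Integer seed.
#' @param max_failures Maximal tolerated fraction of failing resamples
#'   (default 0.01); beyond it an error reports the failure count.
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`,
#'   `p_two_sided`, `n_reps`.
#' @export
bootstrap_ci <- function(data, statistic, n_reps = 10000, ci_level = 0.95,
                         null_value = 0, group = NULL, seed = 1,
                         max_failures = 0.01) {
  if (n_reps < 100) stop("need n_reps >= 100 for a CI")
  is_df <- is.data.frame(data)
  take <- function(idx) {
    if (!is.null(group)) {
      units <- unique(group)
      pick <- unlist(lapply(idx, function(u) which(group == units[u])),
                     use.names = FALSE)
      if (is_df) data[pick, , drop = FALSE] else data[pick]
    } else if (is_df) data[idx, , drop = FALSE] else data[idx]
  }
  n_units <- if (!is.null(group)) length(unique(group))
             else if (is_df) nrow(data) else length(data)
  est <- statistic(take(seq_len(n_units)))
  set.seed(seed)
  draws <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n_units, n_units, replace = TRUE)
    draws[r] <- tryCatch(statistic(take(idx)), error = function(e) NA_real_)
  }
  fail <- sum(!is.finite(draws))
  if (fail > max_failures * n_reps) {
    stop("statistic failed on ", fail, " of ", n_reps, " resamples")
  }
  draws <- draws[is.finite(draws)]
  alpha <- 1 - ci_level
  # Efron percentile interval: (R + 1) * alpha order statistics
  R <- length(draws); s <- sort(draws)
  qs <- c(s[max(1, floor((R + 1) * alpha / 2))],
          s[min(R, ceiling((R + 1) * (1 - alpha / 2)))])
  p <- 2 * min(mean(draws <= null_value), mean(draws >= null_value))
  tibble::tibble(estimate = est, ci_low = qs[1], ci_high = qs[2],
                 p_two_sided = min(max(p, 1 / length(draws)), 1),
                 n_reps = length(draws))
}

#' Spearman rank correlation with Student's t test
#'
#' Spearman's rho on average ranks with the two-sided Student's t test:
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' For `rho = +-1` the p-value is reported as the machine floor with an
#' `exact` note.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @return A one-row tibble: `rho`, `t`, `p_two_sided`, `n`, `exact`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_test() needs n >= 4")
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  if (abs(rho) >= 1 - 1e-15) {
    return(tibble::tibble(rho = sign(rho), t = sign(rho) * Inf,
                          p_two_sided = .Machine$double.xmin, n = n,
                          exact = TRUE))
  }
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  tibble::tibble(rho = rho, t = tt,
                 p_two_sided = 2 * pt(-abs(tt), df = n - 2), n = n,
                 exact = FALSE)
}

#' Steiger's Z for two dependent correlations sharing a variable
#'
#' Tests `H0: rho_jk = rho_jh` for correlations measured on the same `n`
#' cases and sharing variable j (e.g. two predictors of the same
#' segregation outcome), using Fisher z transforms with the shared-variable
#' covariance term and the pooled correlation:
#' `Z = sqrt(n - 3) * (z_jk - z_jh) / sqrt(2 - 2 * c)` where `c` is the
#' covariance of the two transforms implied by `r_kh` and the pooled
#' `rbar = (r_jk + r_jh) / 2`.
#'
#' @param r_jk,r_jh The two correlations being compared.
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return A one-row tibble: `z`, `p_two_sided`.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  if (n <= 3) stop("steiger_z() needs n > 3")
  for (r in c(r_jk, r_jh, r_kh)) {
    if (!is.finite(r) || abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  det3 <- 1 + 2 * r_jk * r_jh * r_kh - r_jk^2 - r_jh^2 - r_kh^2
  if (det3 < -1e-12) {
    stop("infeasible correlation triple: the 3x3 correlation matrix has ",
         "negative determinant ", signif(det3, 4),
         " (not positive semi-definite)")
  }
  fisher <- function(r) atanh(r)
  rbar <- (r_jk + r_jh) / 2
  cov_term <- (r_kh * (1 - 2 * rbar^2) -
                 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)) /
    (1 - rbar^2)^2
  z <- sqrt(n - 3) * (fisher(r_jk) - fisher(r_jh)) /
    sqrt(2 - 2 * cov_term)
  tibble::tibble(z = z, p_two_sided = 2 * pnorm(-abs(z)))
}
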