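#' Fit the random-intercept exposure model by REML
#'
#' Fits `y_ij = a * x_i + b + eps1_i + eps2_ij`, where `x_i` is the
#' (standardized) SES of ego i, `y_ij` the SES of the j-th exposure partner
#' of ego i, `eps1_i ~ N(0, var1)` an ego-level noise term and
#' `eps2_ij ~ N(0, var2)` observation noise. The latent mean partner SES of
#' ego i is `a * x_i + b + eps1_i`; modelling partner values as noisy draws
#' around it is what removes the attenuation bias of the naive correlation
#' under sparse partner samples.
#'
#' Estimation profiles the restricted log-likelihood over the variance
#' ratio `theta = var1/var2` (slope, intercept and `var2` have closed forms
#' given `theta`) and optimizes `theta >= 0` by bounded scalar search with
#' objective tolerance 1e-8; `var1` may sit on the 0 boundary. The fit also
#' carries an ML likelihood-ratio statistic against the i.i.d. null
#' (`a = 0`, `var1 = 0`, i.e. complete random mixing), whose p-value uses
#' the boundary mixture `0.5 chi2_1 + 0.5 chi2_2`; it is consumed by
#' [corrected_exposure_segregation()] to recognise data with no ego-level
#' signal.
#'
#' @param records Ego-exposure records: a tibble with columns `ego`, `x`
#'   (ego SES, standardized), `y` (partner SES), e.g. from
#'   [build_ego_records()].
#' @return An object of class `exposeg_mixfit` with elements `a`, `b`,
#'   `var1`, `var2`, `theta`, `converged`, `n_egos`, `n_obs`,
#'   `null_lrt_stat`, `null_lrt_p` and `degenerate` (`"perfect_fit"`,
#'   `"zero_variance"` or `NA`).
#' @export
fit_mixed_model <- function(records) {
  stopifnot(all(c("ego", "x", "y") %in% names(records)))
  records <- records[is.finite(records$x) & is.finite(records$y), ]
  g <- dplyr::summarise(dplyr::group_by(records, .data$ego),
                        x = .data$x[1], n = dplyr::n(),
                        ybar = mean(.data$y),
                        ssw = sum((.data$y - mean(.data$y))^2),
                        .groups = "drop")
  G <- nrow(g); N <- sum(g$n)
  if (G < 2) stop("need >= 2 egos to fit the mixed model")
  if (all(g$n < 2)) {
    stop("need >= 1 ego with >= 2 partners: var1/var2 are not identifiable")
  }
  if (var(g$x) == 0) stop("zero variance in ego SES; model not estimable")
  ssw_tot <- sum(g$ssw)

  wls <- function(theta) {
    w <- g$n / (1 + g$n * theta)
    sw <- sum(w); swx <- sum(w * g$x); swy <- sum(w * g$ybar)
    swxx <- sum(w * g$x^2); swxy <- sum(w * g$x * g$ybar)
    det <- sw * swxx - swx^2
    a <- (sw * swxy - swx * swy) / det
    b <- (swy - a * swx) / sw
    rss <- ssw_tot + sum(w * (g$ybar - a * g$x - b)^2)
    list(a = a, b = b, rss = rss, det = det, w = w)
  }
  y_scale <- max(var(records$y), 1e-300)

  ## degenerate cases: partner values carry no noise at all
  fit0 <- wls(0)
  if (fit0$rss / N <= 1e-12 * y_scale || y_scale <= 1e-300) {
    a <- fit0$a
    return(new_mixfit(a = a, b = fit0$b, var1 = 0, var2 = fit0$rss / (N - 2),
                      theta = 0, converged = TRUE, n_egos = G, n_obs = N,
                      null_lrt_stat = Inf, null_lrt_p = 0,
                      degenerate = if (abs(a) < 1e-12) "zero_variance"
                                   else "perfect_fit"))
  }

  reml_obj <- function(theta) {
    f <- wls(theta)
    (N - 2) * log(f$rss) + sum(log1p(g$n * theta)) + log(f$det)
  }
  ml_obj <- function(theta) {
    f <- wls(theta)
    N * log(f$rss) + sum(log1p(g$n * theta))
  }
  theta_hat <- profile_minimum(reml_obj)
  fit <- wls(theta_hat)
  var2 <- fit$rss / (N - 2)
  var1 <- theta_hat * var2

  ## ML likelihood-ratio test against the i.i.d. null (a = 0, var1 = 0)
  theta_ml <- profile_minimum(ml_obj)
  fml <- wls(theta_ml)
  rss0 <- sum((records$y - mean(records$y))^2)
  lrt <- N * log(rss0) - N * log(fml$rss) - sum(log1p(g$n * theta_ml))
  lrt <- max(lrt, 0)
  p <- 0.5 * pchisq(lrt, 1, lower.tail = FALSE) +
    0.5 * pchisq(lrt, 2, lower.tail = FALSE)

  new_mixfit(a = fit$a, b = fit$b, var1 = var1, var2 = var2,
             theta = theta_hat, converged = TRUE, n_egos = G, n_obs = N,
             null_lrt_stat = lrt, null_lrt_p = p, degenerate = NA_character_)
}

# Minimize a profile objective over theta >= 0: log-scale golden search via
# optimize(), compared against the theta = 0 boundary.
profile_minimum <- function(obj, tol = 1e-8) {
  opt <- optimize(function(u) obj(exp(u)), interval = c(-30, 15), tol = tol)
  if (obj(0) <= opt$objective + tol) 0 else exp(opt$minimum)
}

new_mixfit <- function(...) structure(list(...), class = "exposeg_mixfit")

#' @export
print.exposeg_mixfit <- function(x, ...) {
  cat("<exposeg_mixfit> a = ", signif(x$a, 4), ", var1 = ",
      signif(x$var1, 4), ", var2 = ", signif(x$var2, 4), " (",
      x$n_egos, " egos, ", x$n_obs, " partner values)\n", sep = "")
  if (!is.na(x$degenerate)) cat("  degenerate: ", x$degenerate, "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted exposure mixed model
#'
#' @param x An `exposeg_mixfit`.
#' @param ... Unused.
#' @return One row per parameter (`slope`, `intercept`, `var_ego`,
#'   `var_resid`) with the estimate.
#' @export
tidy.exposeg_mixfit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept", "var_ego", "var_resid"),
    estimate = c(x$a, x$b, x$var1, x$var2)
  )
}

#' @rdname tidy.exposeg_mixfit
#' @return `glance()`: a one-row model summary.
#' @export
glance.exposeg_mixfit <- function(x, ...) {
  tibble::tibble(n_egos = x$n_egos, n_obs = x$n_obs,
                 converged = x$converged,
                 null_lrt_stat = x$null_lrt_stat,
                 null_lrt_p = x$null_lrt_p, degenerate = x$degenerate)
}
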