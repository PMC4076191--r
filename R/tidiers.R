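# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SSF fit
#'
#' One row per coefficient with naive and (when available) cluster-robust
#' standard errors; confidence intervals and Wald tests use the robust SE if
#' present, the naive SE otherwise.
#'
#' @param x an [fit_clogit()] object.
#' @param conf_level confidence level (default 0.95).
#' @param ... unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `robust_se`,
#'   `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @export
tidy.ssf_fit <- function(x, conf_level = 0.95, ...) {
  if (x$K == 0) {
    return(tibble::tibble(
      term = character(0), estimate = numeric(0),
      std_error = numeric(0), robust_se = numeric(0),
      statistic = numeric(0), p_value = numeric(0),
      conf_low = numeric(0), conf_high = numeric(0)
    ))
  }
  se <- sqrt(diag(x$vcov_naive))
  rse <- if (!is.null(x$vcov_robust)) sqrt(diag(x$vcov_robust)) else NA_real_
  use <- if (!is.null(x$vcov_robust)) sqrt(diag(x$vcov_robust)) else se
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  stat <- x$coefficients / use
  tibble::tibble(
    term = x$terms, estimate = unname(x$coefficients),
    std_error = unname(se), robust_se = unname(rse),
    statistic = unname(stat),
    p_value = 2 * stats::pnorm(-abs(unname(stat))),
    conf_low = unname(x$coefficients - z * use),
    conf_high = unname(x$coefficients + z * use)
  )
}

#' Glance at an SSF fit
#'
#' @param x an [fit_clogit()] object.
#' @param ... unused.
#' @return A one-row tibble: `formula_id`, `k`, `log_lik`, `qic`,
#'   `n_strata`, `n_clusters`, `converged`.
#' @export
glance.ssf_fit <- function(x, ...) {
  tibble::tibble(
    formula_id = x$formula_id, k = x$K, log_lik = x$loglik,
    qic = x$qic %||% NA_real_,
    n_strata = x$n_strata, n_clusters = x$n_clusters %||% NA_integer_,
    converged = x$converged
  )
}

#' Tidy an RSF fit
#'
#' @param x an [rsf_fit()] object.
#' @param ... unused.
#' @return The per-class coefficient tibble (`class`, `beta`, `se`,
#'   `conf_low`, `conf_high`, `separated`).
#' @export
tidy.rsf_fit <- function(x, ...) x$coefs

#' Glance at an RSF fit
#'
#' @param x an [rsf_fit()] object.
#' @param ... unused.
#' @return A one-row tibble with counts and the reference class.
#' @export
glance.rsf_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used, n_available = x$n_available,
    reference_class = x$reference_class,
    n_classes = nrow(x$coefs)
  )
}

#' Tidy a cross-validation result
#'
#' @param x an [kfold_cv()] object.
#' @param ... unused.
#' @return The per-repetition tibble (`rep`, `rs`, `rs_null`).
#' @export
tidy.ssf_cv <- function(x, ...) x$reps

#' Glance at a cross-validation result
#'
#' @param x an [kfold_cv()] object.
#' @param ... unused.
#' @return A one-row tibble with mean r_s, its 95% CI, the null mean and CI
#'   and the bin count.
#' @export
glance.ssf_cv <- function(x, ...) {
  tibble::tibble(
    mean_rs = x$mean_rs, ci_low = x$ci[1], ci_high = x$ci[2],
    null_mean_rs = x$null_mean_rs, null_ci_low = x$null_ci[1],
    null_ci_high = x$null_ci[2], n_bins = x$n_bins,
    n_reps = nrow(x$reps)
  )
}
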