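# k-fold cross-validation for case-control (stratified) designs:
# rank the observed step among its candidates by SSF score, tally ranks
# into bins, and correlate bin index with frequency.

#' Spearman correlation between rank bins and their frequencies
#'
#' Tallies observed-step ranks (possibly midranks from ties) into `n_bins`
#' bins - a half-integer rank splits its mass between the neighbouring bins -
#' and returns the Spearman rank correlation between the bin index
#' `1:n_bins` and the tallied frequencies.
#'
#' @param ranks numeric vector of ranks in `[1, n_bins]` (midranks allowed).
#' @param n_bins number of bins (candidates per stratum).
#' @return Spearman's r_s.
#' @export
rank_bin_spearman <- function(ranks, n_bins) {
  freq <- numeric(n_bins)
  lo <- floor(ranks)
  hi <- ceiling(ranks)
  w_hi <- ranks - lo
  for (i in seq_along(ranks)) {
    if (lo[i] == hi[i]) {
      freq[lo[i]] <- freq[lo[i]] + 1
    } else {
      freq[lo[i]] <- freq[lo[i]] + (1 - w_hi[i])
      freq[hi[i]] <- freq[hi[i]] + w_hi[i]
    }
  }
  stats::cor(seq_len(n_bins), freq, method = "spearman")
}

#' k-fold cross-validation of an SSF
#'
#' Repeatedly fits the model on 80% of randomly selected strata (for
#' `folds = 5`) and scores the withheld 20%: in each held-out stratum the
#' observed step is ranked against its random steps from 1 (lowest score)
#' to the number of candidates (ties get midranks), ranks are tallied into
#' that many bins, and Spearman's r_s is computed between bin rank and
#' frequency. A null r_s is computed per repetition by assigning ranks
#' uniformly at random. Means and percentile 95% CIs over the repetitions
#' are returned.
#'
#' @param table a covariate tibble.
#' @param formula_id see [ssf_terms()].
#' @param folds the held-out fraction is `1/folds` (default 5).
#' @param reps number of random splits (default 100).
#' @param seed RNG seed or `NULL`.
#' @param scorer optional function `(fit, test_table) -> numeric scores`
#'   replacing the fitted linear predictor (used for oracle checks).
#' @return An object of class `ssf_cv`: tibble `reps` with per-rep `rs` and
#'   `rs_null`, plus `mean_rs`, `ci` (2.5/97.5 percentiles), `null_mean_rs`,
#'   `null_ci`, `n_bins`, and the pooled bin frequencies `bin_freq`.
#' @export
kfold_cv <- function(table, formula_id = "environment", folds = 5,
                     reps = 100, seed = NULL, scorer = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strata <- unique(table$stratum)
  ns <- length(strata)
  if (ns < folds) stop("fewer strata than folds", call. = FALSE)
  m <- max(table(table$stratum))
  rs <- numeric(reps)
  rs_null <- numeric(reps)
  bin_freq <- numeric(m)
  for (r in seq_len(reps)) {
    test_n <- max(1L, round(ns / folds))
    test_s <- sample(strata, test_n)
    train <- table[!table$stratum %in% test_s, ]
    test <- table[table$stratum %in% test_s, ]
    fit <- fit_clogit(train, formula_id)
    score <- if (is.null(scorer)) {
      as.vector(as.matrix(test[fit$terms]) %*% fit$coefficients)
    } else {
      scorer(fit, test)
    }
    sid <- factor(test$stratum, levels = unique(test$stratum))
    rk <- stats::ave(score, sid, FUN = rank) # midranks on ties
    obs_rk <- rk[test$case == 1]
    rs[r] <- rank_bin_spearman(obs_rk, m)
    rs_null[r] <- rank_bin_spearman(sample.int(m, length(obs_rk),
      replace = TRUE
    ), m)
    f <- numeric(m)
    ir <- round(obs_rk)
    for (b in ir) f[b] <- f[b] + 1
    bin_freq <- bin_freq + f
  }
  structure(
    list(
      reps = tibble::tibble(rep = seq_len(reps), rs = rs, rs_null = rs_null),
      mean_rs = mean(rs),
      ci = stats::quantile(rs, c(0.025, 0.975), names = FALSE),
      null_mean_rs = mean(rs_null),
      null_ci = stats::quantile(rs_null, c(0.025, 0.975), names = FALSE),
      n_bins = m, bin_freq = bin_freq / reps,
      formula_id = if (length(formula_id) == 1) formula_id else "custom"
    ),
    class = "ssf_cv"
  )
}

#' @export
print.ssf_cv <- function(x, ...) {
  cat(
    "<ssf_cv> ", x$formula_id, " model, ", nrow(x$reps), " reps, ",
    x$n_bins, " rank bins\n",
    "  r_s = ", round(x$mean_rs, 3), " (95% CI ", round(x$ci[1], 3), " to ",
    round(x$ci[2], 3), "); null r_s = ", round(x$null_mean_rs, 3),
    " (", round(x$null_ci[1], 3), " to ", round(x$null_ci[2], 3), ")\n",
    sep = ""
  )
  invisible(x)
}
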