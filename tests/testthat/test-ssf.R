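test_that("independence partition applies the block, gap and merge rules", {
  tab <- synth_strata(26, c(cos_t_mem = 0.5), seed = 41)
  part <- build_independence_partition(tab, block_len = 24, gap = 2)
  expect_equal(sum(part$kept), 24)
  expect_equal(sum(!part$kept), 2)
  expect_equal(length(unique(part$cluster[part$kept])), 1)

  # two individuals 50 m apart at one timestamp share a cluster
  t0 <- as.POSIXct("2009-01-05 00:00:00", tz = "UTC")
  mk <- function(id, x0) {
    tibble::tibble(
      stratum = paste0(id, "_", 1:6), id = id,
      t = t0 + 14400 * (1:6), case = 1L,
      x0 = x0, y0 = 0
    )
  }
  near <- dplyr::bind_rows(mk("a", 0), mk("b", 50))
  pn <- build_independence_partition(near, block_len = 24, gap = 2)
  expect_equal(length(unique(pn$cluster)), 1)

  far <- dplyr::bind_rows(mk("a", 0), mk("b", 500))
  pf <- build_independence_partition(far, block_len = 24, gap = 2)
  expect_equal(length(unique(pf$cluster)), 2)
  expect_error(build_independence_partition(near, block_len = 0), "block_len")
})

test_that("conditional logit matches a dense grid-search maximizer", {
  # small binary-covariate problem solved to 1e-4 by brute force
  set.seed(42)
  tab <- synth_strata(30, c(x = 1.2), m = 5)
  tab$x <- round(tab$x) > 0 # binary covariate
  tab$x <- as.numeric(tab$x)
  fit <- fit_clogit(tab, "x")
  b_grid <- oracle_clogit_1d(tab$x, tab$case, tab$stratum)
  expect_lt(abs(coef(fit) - b_grid), 1e-4)

  # flat likelihood errors out
  flat <- tab
  flat$x <- 1
  expect_error(fit_clogit(flat, "x"), "flat|constant")
})

test_that("conditional logit agrees with the survival package on shared data", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  tab <- synth_strata(120, c(x1 = 0.8, x2 = -0.4), seed = 43)
  fit <- fit_clogit(tab, c("x1", "x2"))
  ref <- survival::clogit(case ~ x1 + x2 + strata(stratum), data = tab)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(diag(fit$vcov_naive)), unname(diag(vcov(ref))),
    tolerance = 1e-4
  )
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("known coefficients are recovered from simulated strata", {
  tab <- synth_strata(500, c(x1 = 1.0, x2 = -0.5), seed = 44)
  fit <- fit_clogit(tab, c("x1", "x2"))
  se <- sqrt(diag(fit$vcov_naive))
  expect_true(all(abs(coef(fit) - c(1.0, -0.5)) < 3 * se))
})

test_that("conditional likelihood ignores stratum-constant shifts", {
  tab <- synth_strata(60, c(x1 = 0.7), seed = 45)
  fit0 <- fit_clogit(tab, "x1")
  shifted <- tab
  shift <- stats::setNames(
    rnorm(length(unique(tab$stratum))), unique(tab$stratum)
  )
  shifted$x1 <- shifted$x1 + shift[shifted$stratum]
  fit1 <- fit_clogit(shifted, "x1")
  expect_equal(coef(fit0), coef(fit1), tolerance = 1e-6)
  expect_equal(fit0$loglik, fit1$loglik, tolerance = 1e-8)
})

test_that("sandwich covariance responds correctly to cluster structure", {
  tab <- synth_strata(200, c(x1 = 0.6, x2 = -0.3), seed = 46)
  fit <- fit_clogit(tab, c("x1", "x2"))
  # independent well-specified data: robust ~ naive
  fit <- sandwich_covariance(fit) # singleton clusters
  ratio <- sqrt(diag(fit$vcov_robust)) / sqrt(diag(fit$vcov_naive))
  expect_true(all(ratio > 0.8 & ratio < 1.2))

  # duplicating every stratum (as its own cluster) halves the covariance
  dup <- tab
  dup$stratum <- paste0(dup$stratum, "_copy")
  both <- dplyr::bind_rows(tab, dup)
  fit2 <- sandwich_covariance(fit_clogit(both, c("x1", "x2")))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
  expect_equal(fit2$vcov_robust, fit$vcov_robust / 2, tolerance = 0.02)

  # everything in one cluster: score sums to zero at the MLE
  one <- tibble::tibble(
    stratum = unique(tab$stratum),
    cluster = "all"
  )
  expect_error(sandwich_covariance(fit_clogit(tab, c("x1", "x2")), one),
    "degenerate"
  )
})

test_that("QIC reduces to its closed forms", {
  tab <- synth_strata(50, c(x1 = 0.5), m = 21, seed = 47)
  # null model: 2 * n * log(21)
  null <- qic(fit_clogit(tab, character(0)))
  expect_equal(null$qic, 2 * 50 * log(21))

  # independence regime: QIC within 5% of AIC
  fit <- qic(sandwich_covariance(fit_clogit(tab, "x1")))
  aic <- -2 * fit$loglik + 2 * fit$K
  expect_lt(abs(fit$qic - aic) / aic, 0.05)
  expect_error(qic(fit_clogit(tab, "x1")), "sandwich")
})

test_that("model selection weights are normalized and rank by QIC", {
  tab <- demo_table()
  part <- build_independence_partition(tab)
  sel <- model_select(tab, part)
  expect_equal(sum(sel$weight), 1, tolerance = 1e-12)
  expect_equal(sel$dqic[1], 0)
  expect_true(all(diff(sel$qic) >= 0))
  expect_setequal(sel$model, c("memory", "energetic", "environment"))
  expect_error(model_select(tab, part, formulas = "memory"), ">= 2")
})

test_that("VIF flags engineered collinearity at its textbook value", {
  set.seed(48)
  n <- 4000
  tab <- tibble::tibble(
    stratum = rep(paste0("s", 1:(n / 4)), each = 4),
    case = rep(c(1L, 0L, 0L, 0L), n / 4),
    a = rnorm(n), b = rnorm(n), c = rnorm(n)
  )
  v <- vif(tab, c("a", "b", "c"))
  expect_true(all(abs(v$vif - 1) < 0.05)) # independent covariates

  # x2 = x1 + noise tuned to R^2 = 0.75 -> VIF ~ 4
  tab$d <- tab$a + rnorm(n, 0, sqrt(1 / 3))
  v2 <- vif(tab, c("a", "d", "b"))
  expect_equal(v2$vif[v2$term == "d"], 4, tolerance = 0.35)

  # exact duplicate -> infinite VIF
  tab$e <- tab$a
  v3 <- vif(tab, c("a", "e"))
  expect_true(all(is.infinite(v3$vif)))
})

test_that("tidy and glance expose the fit in broom shape", {
  tab <- synth_strata(80, c(x1 = 0.6, x2 = -0.2), seed = 49)
  fit <- qic(sandwich_covariance(fit_clogit(tab, c("x1", "x2"))))
  td <- tidy(fit)
  expect_equal(td$term, c("x1", "x2"))
  expect_true(all(c("estimate", "robust_se", "conf_low", "p_value")
  %in% names(td)))
  expect_true(all(td$conf_low < td$estimate & td$estimate < td$conf_high))
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_equal(gl$n_strata, 80L)
  expect_false(is.na(gl$qic))
})
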