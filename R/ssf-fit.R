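# Conditional logistic SSF estimation with cluster-robust inference.
#
# The conditional likelihood treats each stratum (1 observed step + its
# random controls, sharing a start point) as a matched set:
#   l(beta) = sum_s [ beta'x_obs - log sum_{j in s} exp(beta'x_j) ].
# Maximisation is Newton-Raphson with step-halving; the naive covariance is
# the inverse observed information, and the sandwich estimator sums scores
# over user-supplied independence clusters.

#' Candidate model formulas
#'
#' The three nested SSF candidate models: `memory` (the memory direction
#' term only), `energetic` (adds the gain/loss ratio and its interaction
#' with the 72 h energy balance), and `environment` (all ten terms,
#' adding canopy cover, altitude, edge, the three disturbance terms and the
#' cover-by-energy interaction).
#'
#' @param formula_id `"memory"`, `"energetic"` or `"environment"`, or a
#'   character vector of covariate column names for a custom model.
#' @return character vector of covariate names.
#' @export
ssf_terms <- function(formula_id) {
  if (length(formula_id) != 1 ||
    !formula_id %in% c("memory", "energetic", "environment")) {
    return(formula_id)
  }
  switch(formula_id,
    memory = "cos_t_mem",
    energetic = c("cos_t_mem", "g_over_l", "gl_x_de"),
    environment = ssf_covariate_names()
  )
}

# internal: conditional log-likelihood, score and information at beta
clogit_parts <- function(X, y, strata, beta) {
  eta <- as.vector(X %*% beta)
  sid <- as.integer(factor(strata, levels = unique(strata)))
  ns <- max(sid)
  # per-stratum log-sum-exp, overflow-guarded
  smax <- as.vector(tapply(eta, sid, max))
  w <- exp(eta - smax[sid])
  denom <- as.vector(rowsum(w, sid))
  lse <- log(denom) + smax
  p <- w / denom[sid]
  ll <- sum(eta[y == 1]) - sum(lse)
  score <- as.vector(crossprod(X, y - p))
  Mu <- rowsum(p * X, sid) # per-stratum E[x]
  info <- crossprod(sqrt(p) * X) - crossprod(Mu)
  # per-stratum score contributions u_s = x_obs - E[x]
  U <- X[y == 1, , drop = FALSE] - Mu
  list(ll = ll, score = score, info = info, U = U, p = p, sid = sid, ns = ns)
}

#' Fit a conditional logistic step-selection function
#'
#' Maximises the stratified conditional likelihood by Newton-Raphson with
#' step-halving (convergence when the log-likelihood changes by less than
#' `tol`). Errors when the covariates carry no within-stratum variation
#' (flat likelihood, coefficients unidentifiable) and warns on apparent
#' monotone likelihood (separation).
#'
#' @param table a covariate tibble from [replay_track()] (columns `stratum`,
#'   `case` and the covariates).
#' @param formula_id see [ssf_terms()].
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter Newton-Raphson iteration cap.
#' @return An object of class `ssf_fit`: coefficients, naive covariance
#'   (`vcov_naive`), observed information (`info`), log conditional
#'   likelihood, stratum count, and (once [sandwich_covariance()] /
#'   [qic()] are applied) robust covariance and QIC.
#' @export
#' @examples
#' tab <- synth_strata(n_strata = 80, beta = c(cos_t_mem = 0.8), seed = 1)
#' fit <- fit_clogit(tab, "memory")
#' coef(fit)
fit_clogit <- function(table, formula_id = "environment", tol = 1e-8,
                       max_iter = 100) {
  terms <- ssf_terms(formula_id)
  K <- length(terms)
  y <- table$case
  strata <- table$stratum
  if (K == 0) {
    # null model: every stratum contributes log(1/n_s)
    ns <- table(strata)
    ll <- -sum(log(ns))
    return(structure(
      list(
        coefficients = numeric(0), vcov_naive = matrix(0, 0, 0),
        info = matrix(0, 0, 0), loglik = ll, n_strata = length(ns),
        K = 0L, formula_id = "null", converged = TRUE,
        terms = character(0), X = NULL, y = y, strata = strata
      ),
      class = "ssf_fit"
    ))
  }
  miss <- setdiff(terms, names(table))
  if (length(miss)) {
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  X <- as.matrix(table[terms])
  # identifiability: require within-stratum variation
  wsv <- vapply(seq_len(K), function(j) {
    any(stats::ave(X[, j], strata, FUN = function(v) max(v) - min(v)) > 0)
  }, logical(1))
  if (!any(wsv)) {
    stop("all covariates constant within every stratum; ",
      "conditional likelihood is flat",
      call. = FALSE
    )
  }

  beta <- rep(0, K)
  parts <- clogit_parts(X, y, strata, beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(parts$info, parts$score), error = function(e) {
      stop("singular information matrix (collinear or constant covariates)",
        call. = FALSE
      )
    })
    # step-halving on likelihood decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      new_parts <- clogit_parts(X, y, strata, cand)
      if (new_parts$ll >= parts$ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    dll <- abs(new_parts$ll - parts$ll)
    beta <- beta + lam * step
    parts <- new_parts
    if (dll < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Newton-Raphson did not converge in ", max_iter, " iterations",
      call. = FALSE
    )
  }
  if (any(abs(beta) > 30)) {
    warning("very large coefficient(s): possible complete separation ",
      "(monotone likelihood)",
      call. = FALSE
    )
  }
  names(beta) <- terms
  vc <- solve(parts$info)
  dimnames(vc) <- list(terms, terms)
  structure(
    list(
      coefficients = beta, vcov_naive = vc, info = parts$info,
      loglik = parts$ll, n_strata = parts$ns, K = K,
      formula_id = if (length(formula_id) == 1) formula_id else "custom",
      converged = converged, terms = terms,
      X = X, y = y, strata = strata
    ),
    class = "ssf_fit"
  )
}

#' @export
coef.ssf_fit <- function(object, ...) object$coefficients

#' @export
vcov.ssf_fit <- function(object, robust = FALSE, ...) {
  if (robust) {
    if (is.null(object$vcov_robust)) {
      stop("no sandwich covariance; run sandwich_covariance() first",
        call. = FALSE
      )
    }
    object$vcov_robust
  } else {
    object$vcov_naive
  }
}

#' @export
logLik.ssf_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, class = "logLik")
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat("<ssf_fit> ", x$formula_id, " model: K = ", x$K, ", ", x$n_strata,
    " strata, logLik = ", format(x$loglik, digits = 6), "\n",
    sep = ""
  )
  if (x$K > 0) {
    se <- sqrt(diag(x$vcov_naive))
    print(round(cbind(beta = x$coefficients, se = se), 4))
  }
  if (!is.null(x$qic)) cat("QIC =", format(x$qic, digits = 7), "\n")
  invisible(x)
}

#' Independence partition of strata
#'
#' Groups strata into clusters for the sandwich variance. Within each
#' individual, consecutive strata form blocks of `block_len`; the `gap`
#' strata after each block are dropped from fitting so that consecutive
#' clusters are separated by at least `gap` steps (8 h at the default).
#' Simultaneous strata of two individuals whose start points lie within
#' `proximity` metres have their containing blocks merged (union-find), so
#' non-independent animals share a cluster.
#'
#' @param table a covariate tibble (only `case == 1` rows are used for the
#'   stratum ordering and start points).
#' @param block_len,gap,proximity see [movement_config()] `ssf` entry.
#' @return A tibble with one row per stratum: `stratum`, `cluster`
#'   (character id), `kept` (logical; `FALSE` for gap strata).
#' @export
build_independence_partition <- function(table, block_len = 24, gap = 2,
                                         proximity = 100) {
  if (block_len < 1) stop("block_len must be >= 1", call. = FALSE)
  obs <- table[table$case == 1, c("stratum", "id", "t", "x0", "y0")]
  obs <- obs[order(obs$id, obs$t), ]
  per <- split(seq_len(nrow(obs)), obs$id)
  cluster <- character(nrow(obs))
  kept <- logical(nrow(obs))
  for (id in names(per)) {
    idx <- per[[id]]
    pos <- seq_along(idx) - 1L
    blk <- pos %/% (block_len + gap)
    within <- pos %% (block_len + gap)
    kept[idx] <- within < block_len
    cluster[idx] <- paste0(id, "#", blk)
  }
  # union-find merge of blocks with simultaneous nearby individuals
  parent <- stats::setNames(nm = unique(cluster))
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  by_t <- split(seq_len(nrow(obs)), as.character(obs$t))
  for (ii in by_t) {
    if (length(ii) < 2) next
    for (a in seq_along(ii)[-1]) {
      for (b in seq_len(a - 1)) {
        i <- ii[a]
        j <- ii[b]
        if (obs$id[i] == obs$id[j]) next
        d <- sqrt((obs$x0[i] - obs$x0[j])^2 + (obs$y0[i] - obs$y0[j])^2)
        if (d < proximity) {
          ra <- find(cluster[i])
          rb <- find(cluster[j])
          if (ra != rb) parent[[ra]] <- rb
        }
      }
    }
  }
  cluster <- vapply(cluster, find, character(1))
  tibble::tibble(stratum = obs$stratum, cluster = unname(cluster), kept = kept)
}

#' Cluster-robust sandwich covariance
#'
#' `A^-1 B A^-1`, where `A` is the observed information of the independence
#' likelihood at the fitted coefficients and `B` sums, over independence
#' clusters, the outer products of cluster score sums. With one cluster per
#' stratum and a correctly specified model this approaches the naive
#' covariance; with everything in one cluster the score sum is zero at the
#' MLE and the estimator degenerates (an error).
#'
#' @param fit an [fit_clogit()] object.
#' @param partition a tibble from [build_independence_partition()] (or any
#'   tibble with `stratum` and `cluster`); strata missing from it form
#'   singleton clusters.
#' @return The fit, with `vcov_robust` filled in.
#' @export
sandwich_covariance <- function(fit, partition = NULL) {
  if (fit$K == 0) stop("null model has no covariance", call. = FALSE)
  parts <- clogit_parts(fit$X, fit$y, fit$strata, fit$coefficients)
  us <- parts$U # one row per stratum, order = first appearance
  sn <- unique(fit$strata)
  cl <- sn
  if (!is.null(partition)) {
    m <- match(sn, partition$stratum)
    cl[!is.na(m)] <- partition$cluster[m[!is.na(m)]]
  }
  G <- rowsum(us, cl)
  B <- crossprod(G)
  if (all(abs(B) < 1e-10)) {
    stop("degenerate sandwich: all strata share one cluster ",
      "(score sums to zero at the MLE)",
      call. = FALSE
    )
  }
  Ainv <- solve(parts$info)
  fit$vcov_robust <- Ainv %*% B %*% Ainv
  dimnames(fit$vcov_robust) <- dimnames(fit$vcov_naive)
  fit$n_clusters <- length(unique(cl))
  fit
}

#' Quasi-likelihood under independence criterion
#'
#' `QIC = -2 l(beta) + 2 trace(A V_r)` where `l` is the independence
#' conditional log-likelihood, `A` the observed information and `V_r` the
#' cluster-robust covariance. When `V_r = A^-1` the trace is the parameter
#' count and QIC reduces to AIC. For the null model (no covariates) QIC is
#' `2 n log(m)` with `m` candidates per stratum.
#'
#' @param fit an [fit_clogit()] object with a sandwich covariance (see
#'   [sandwich_covariance()]); the null model needs none.
#' @return The fit with `qic` (and `qic_trace`) filled in.
#' @export
qic <- function(fit) {
  if (fit$K == 0) {
    fit$qic <- -2 * fit$loglik
    fit$qic_trace <- 0
    return(fit)
  }
  if (is.null(fit$vcov_robust)) {
    stop("run sandwich_covariance() before qic()", call. = FALSE)
  }
  tr <- sum(diag(fit$info %*% fit$vcov_robust))
  fit$qic <- -2 * fit$loglik + 2 * tr
  fit$qic_trace <- tr
  fit
}

#' QIC model selection across the candidate SSFs
#'
#' Fits each candidate model, attaches the sandwich covariance over the
#' given independence partition (gap strata are dropped from fitting), and
#' ranks models by QIC with Akaike-style weights
#' `w_i = exp(-dQIC_i/2) / sum_j exp(-dQIC_j/2)`. Candidates that fail to
#' fit are reported with `NA` and excluded from the weights.
#'
#' @param table a covariate tibble.
#' @param partition optional [build_independence_partition()] result; when
#'   supplied, only `kept` strata are fitted.
#' @param formulas candidate ids, see [ssf_terms()].
#' @return A tibble (`model`, `K`, `loglik`, `qic`, `dqic`, `weight`,
#'   `converged`) sorted by QIC, with the fits in attribute `"fits"`.
#' @export
model_select <- function(table, partition = NULL,
                         formulas = c("memory", "energetic", "environment")) {
  if (length(formulas) < 2) stop("need >= 2 candidate models", call. = FALSE)
  tab <- table
  if (!is.null(partition)) {
    keep <- partition$stratum[partition$kept]
    tab <- tab[tab$stratum %in% keep, ]
  }
  fits <- lapply(formulas, function(f) {
    tryCatch(
      qic(sandwich_covariance(fit_clogit(tab, f), partition)),
      error = function(e) structure(list(msg = conditionMessage(e)),
        class = "ssf_fit_failure"
      )
    )
  })
  names(fits) <- formulas
  ok <- !vapply(fits, inherits, logical(1), "ssf_fit_failure")
  res <- tibble::tibble(
    model = formulas,
    K = vapply(fits, function(f) if (inherits(f, "ssf_fit")) f$K else NA_integer_, integer(1)),
    loglik = vapply(fits, function(f) if (inherits(f, "ssf_fit")) f$loglik else NA_real_, numeric(1)),
    qic = vapply(fits, function(f) if (inherits(f, "ssf_fit")) f$qic else NA_real_, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1))
  )
  res$dqic <- unname(res$qic - min(res$qic, na.rm = TRUE))
  ew <- exp(-res$dqic / 2)
  res$weight <- ew / sum(ew, na.rm = TRUE)
  res <- res[order(res$qic), c(
    "model", "K", "loglik", "qic", "dqic",
    "weight", "converged"
  )]
  attr(res, "fits") <- fits
  res
}

#' Variance inflation factors
#'
#' Screens the covariates of a candidate model for multicollinearity:
#' `VIF_i = 1 / (1 - R2_i)` from regressing covariate i on the others over
#' the control rows. Perfect collinearity is reported as `Inf`.
#'
#' @param table a covariate tibble.
#' @param formula_id see [ssf_terms()].
#' @return A tibble (`term`, `vif`).
#' @export
vif <- function(table, formula_id = "environment") {
  terms <- ssf_terms(formula_id)
  ctrl <- table[table$case == 0, terms, drop = FALSE]
  if (nrow(ctrl) < length(terms) + 1) {
    stop("too few control rows for VIF", call. = FALSE)
  }
  X <- as.matrix(ctrl)
  v <- vapply(seq_along(terms), function(i) {
    yi <- X[, i]
    if (stats::var(yi) == 0) {
      return(NA_real_)
    }
    others <- X[, -i, drop = FALSE]
    if (ncol(others) == 0) {
      return(1)
    }
    fit <- stats::lm.fit(cbind(1, others), yi)
    r2 <- 1 - sum(fit$residuals^2) / sum((yi - mean(yi))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = terms, vif = v)
}

#' Simulate strata from the conditional-logit generative model
#'
#' Draws strata of `m` candidate steps with independent covariates and
#' samples the case in each stratum with probability proportional to
#' `exp(beta'x)` - the exact generative model of the conditional logistic
#' likelihood. Used for parameter-recovery and self-consistency checks.
#'
#' @param n_strata number of strata.
#' @param beta named numeric vector of true coefficients; names become
#'   covariate columns.
#' @param m candidates per stratum (default 21).
#' @param sd standard deviation of the simulated covariates.
#' @param seed RNG seed or `NULL`.
#' @return A covariate tibble with columns `stratum`, `case` and one column
#'   per name of `beta`.
#' @export
synth_strata <- function(n_strata, beta, m = 21, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(beta)
  nm <- names(beta) %||% paste0("x", seq_len(K))
  n <- n_strata * m
  X <- matrix(stats::rnorm(n * K, 0, sd), n, K, dimnames = list(NULL, nm))
  sid <- rep(seq_len(n_strata), each = m)
  eta <- as.vector(X %*% beta)
  case <- integer(n)
  for (s in seq_len(n_strata)) {
    ii <- which(sid == s)
    p <- exp(eta[ii] - max(eta[ii]))
    case[ii[sample.int(m, 1, prob = p)]] <- 1L
  }
  out <- tibble::tibble(
    stratum = paste0("s", sid), id = "sim", case = case,
    t = as.POSIXct("2009-01-01", tz = "UTC") + 14400 * sid,
    x0 = 0, y0 = 0
  )
  dplyr::bind_cols(out, tibble::as_tibble(X))
}
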