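test_that("95% MCP trims outliers and matches the hull oracle", {
  set.seed(101)
  # 95 points in the unit square (metres), 5 outliers 1000 m away
  core <- cbind(runif(95), runif(95))
  out <- cbind(1000 + runif(5), 1000 + runif(5))
  hr <- mcp95(rbind(core, out))
  expect_equal(hr$area_km2 * 1e6, oracle_hull_area(core), tolerance = 1e-9)
  expect_lt(hr$area_km2 * 1e6, 1) # about the unit square, outliers gone

  # all points identical -> degenerate zero area
  same <- matrix(5, 10, 2)
  expect_equal(mcp95(same)$area_km2, 0)
  expect_true(mcp95(same)$degenerate)
  expect_error(mcp95(matrix(0, 2, 2)), "at least 3")

  # random point sets match the independent hull implementation exactly
  for (i in 1:5) {
    pts <- cbind(rnorm(20, 0, 800), rnorm(20, 0, 800))
    expect_equal(
      mcp95(pts, level = 1)$area_km2 * 1e6,
      oracle_hull_area(pts)
    )
  }
})

test_that("MCP area is invariant under rigid motions", {
  set.seed(102)
  pts <- cbind(rnorm(60, 0, 500), rnorm(60, 0, 500))
  base <- mcp95(pts)$area_km2
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- pts %*% rot + matrix(runif(2, -1e4, 1e4), 60, 2, byrow = TRUE)
    expect_equal(mcp95(moved)$area_km2, base, tolerance = 1e-9)
  }
})

test_that("the home-range index is zero at equality and antisymmetric", {
  expect_equal(homerange_index(10, 10), 0)
  expect_equal(homerange_index(2, 1), 1)
  expect_equal(homerange_index(1, 2), -1)
  set.seed(103)
  a <- runif(50, 0.1, 100)
  b <- runif(50, 0.1, 100)
  expect_equal(homerange_index(a, b), -homerange_index(b, a))
  expect_error(homerange_index(0, 1), "positive")
})

test_that("RSF recovers a constructed selection ratio", {
  # two-class landscape, class 11 used at odds 2:1 relative to availability
  cfg <- movement_config()
  ct <- matrix(9L, 100, 100)
  ct[, 51:100] <- 11L # half the extent each
  g <- landscape_grid(ct, config = cfg)
  set.seed(104)
  n <- 1e4
  in_11 <- runif(n) < 2 / 3 # odds 2:1 for equal availability
  x <- ifelse(in_11, runif(n, 1250, 2500), runif(n, 0, 1250))
  used <- tibble::tibble(x = x, y = runif(n, 0, 2500))
  rsf <- rsf_fit(used, polygon = NULL, grid = g, n_random = 2e4, seed = 105)
  row <- rsf$coefs[rsf$coefs$class == 11, ]
  expect_lt(abs(row$beta - log(2)), 3 * row$se)
  expect_equal(rsf$reference_class, 9L)

  # use identical to availability: null calibration
  null_used <- tibble::tibble(
    x = runif(2000, 0, 2500), y = runif(2000, 0, 2500)
  )
  nr <- rsf_fit(null_used, polygon = NULL, grid = g, seed = 106)
  nrow11 <- nr$coefs[nr$coefs$class == 11, ]
  expect_lt(abs(nrow11$beta), 3 * nrow11$se)

  td <- tidy(rsf)
  expect_true(all(c("class", "beta", "se") %in% names(td)))
  expect_equal(glance(rsf)$n_used, n)
})

test_that("availability sampling respects the polygon", {
  g <- landscape_grid(matrix(11L, 80, 80))
  poly <- cbind(c(200, 1200, 1200, 200), c(200, 200, 900, 900))
  set.seed(107)
  used <- tibble::tibble(x = runif(50, 300, 1100), y = runif(50, 300, 800))
  rsf <- rsf_fit(used, polygon = poly, grid = g, n_random = 500)
  expect_equal(rsf$n_available, 500)
  # a one-class availability domain leaves no contrast classes
  expect_equal(nrow(rsf$coefs), 0)
})

test_that("beta-vector correlations hit their closed-form endpoints", {
  mk <- function(beta, lo = beta - 1, hi = beta + 1) {
    structure(
      list(coefs = tibble::tibble(
        class = seq_along(beta), beta = beta, se = 0.5,
        conf_low = lo, conf_high = hi, separated = FALSE
      )),
      class = "rsf_fit"
    )
  }
  real <- mk(c(1, -2, 0.5, 3, -1))
  expect_equal(
    compare_beta_vectors(real, list(real))$pearson, 1
  )
  neg <- mk(-c(1, -2, 0.5, 3, -1))
  cmp <- compare_beta_vectors(real, list(neg))
  expect_equal(cmp$pearson, -1)
  expect_equal(cmp$spearman, -1)

  # hand-built vectors against the independent correlation oracle
  simv <- mk(c(0.3, -1.5, 1.1, 2.0, -0.2))
  got <- compare_beta_vectors(real, list(simv))
  expect_equal(got$spearman,
    oracle_spearman(real$coefs$beta, simv$coefs$beta),
    tolerance = 1e-12
  )
  expect_equal(got$pearson,
    cor(real$coefs$beta, simv$coefs$beta),
    tolerance = 1e-12
  )

  # invariance under a common permutation of coefficient order
  perm <- sample(5)
  real_p <- mk(real$coefs$beta[perm])
  sim_p <- mk(simv$coefs$beta[perm])
  got_p <- compare_beta_vectors(real_p, list(sim_p))
  expect_equal(got_p$pearson, got$pearson)
  expect_equal(got_p$spearman, got$spearman)

  # significant mode keeps only CIs excluding zero; < 3 shared -> flagged
  real_sig <- mk(c(1, -2, 0.1, 0.2, 0.3),
    lo = c(0.5, -2.5, -1, -1, -1), hi = c(1.5, -1.5, 1, 1, 1)
  )
  flagged <- compare_beta_vectors(real_sig, list(simv), mode = "significant")
  expect_false(flagged$defined)
  expect_equal(flagged$n_shared, 2)
})

test_that("scenario contrasts detect constructed selection shifts", {
  cfg <- movement_config()
  land <- synth_landscape(
    seed = 108, nrows = 80, ncols = 80,
    class_mixture = c("9" = 0.4, "11" = 0.3, "12" = 0.3),
    n_roads = 0, n_cuts = 0
  )
  set.seed(109)
  mk_run <- function(pref12) {
    # synthetic location sets: preference for class 12 differs by scenario
    cells <- which(land$grid$cover_type > 0, arr.ind = TRUE)
    w <- ifelse(land$grid$cover_type[cells] == 12L, pref12, 1)
    pick <- cells[sample.int(nrow(cells), 400, replace = TRUE, prob = w), ]
    ctr <- cell_center(land$grid, pick[, 1], pick[, 2])
    tibble::tibble(
      id = rep(c("i1", "i2"), each = 200),
      x = ctr[, 1] + runif(400, -10, 10), y = ctr[, 2] + runif(400, -10, 10)
    )
  }
  runs_a <- lapply(1:4, function(i) mk_run(1))
  runs_b <- lapply(1:4, function(i) mk_run(6))
  sc <- scenario_contrast(runs_a, runs_b, land$grid, land$grid,
    n_random = 2000, seed = 110
  )
  t12 <- sc$beta_tests[sc$beta_tests$class == 12, ]
  expect_lt(t12$p_value, 0.05)
  expect_true(all(c("a", "b") %in% sc$beta$scenario))
  expect_false(any(is.na(sc$area_test$p_value)))

  # identical location sets: no detectable difference anywhere
  same <- scenario_contrast(runs_a, runs_a, land$grid, land$grid,
    n_random = 2000, seed = 111
  )
  expect_true(all(same$beta_tests$p_value[!same$beta_tests$excluded] > 0.05,
    na.rm = TRUE
  ))
})
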