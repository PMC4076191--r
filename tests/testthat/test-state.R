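test_that("intake follows the saturating functional response", {
  expect_equal(intake(40), 61.3 / 2) # half-maximal at V = b
  expect_equal(intake(0), 0)
  expect_lt(abs(intake(1e6) - 61.3) / 61.3, 0.001)

  # monotone and bounded above by a
  set.seed(1)
  v <- sort(runif(200, 0, 5000))
  x <- intake(v)
  expect_true(all(diff(x) > 0))
  expect_true(all(x < 61.3))
  expect_error(intake(-1), "non-negative")
})

test_that("gain converts grams at 7.79 kJ/g and caps at availability", {
  # 10 grams ingested -> 77.9 kJ: X chosen so X * mass * 4/24 = 10
  g <- gain(X = 10 * 24 / (100 * 4), body_mass = 100, step_hours = 4)
  expect_equal(g$ingested_g, 10)
  expect_equal(g$G, 77.9)
  expect_equal(gain(0)$G, 0)

  # maximal intake over a 4 h step at 100 kg
  g2 <- gain(61.3, body_mass = 100, step_hours = 4)
  expect_equal(g2$ingested_g, 61.3 * 100 * 4 / 24, tolerance = 1e-12)
  expect_equal(g2$G, 7.79 * 61.3 * 100 / 6, tolerance = 1e-12)

  # feeding mode caps at the cell content
  g3 <- gain(61.3, body_mass = 100, available_g = 50)
  expect_equal(g3$ingested_g, 50)
  expect_equal(g3$G, 7.79 * 50)
})

test_that("loss sums BMR, distance and ascent terms", {
  expect_equal(loss(0, 0, bmr_per_step = 1500), 1500)
  l1 <- loss(500, 0, bmr_per_step = 1500, c_dist = 0.2)
  l2 <- loss(1000, 0, bmr_per_step = 1500, c_dist = 0.2)
  expect_equal(l2 - 1500, 2 * (l1 - 1500)) # distance term is linear
  # descent costs no climb energy
  expect_equal(
    loss(100, -50, c_climb = 2.7),
    loss(100, 0, c_climb = 2.7)
  )
  expect_gt(loss(100, 50), loss(100, 0))
  expect_error(loss(10, bmr_per_step = 0), "bmr_per_step")
})

test_that("the energy ledger is a strict 18-step FIFO", {
  st <- agent_state(0, 0)
  for (i in 1:18) st <- update_ledger(st, 1, 0)
  expect_equal(delta_e(st), 18)
  st <- update_ledger(st, 1, 0) # 19th push evicts the oldest
  expect_equal(delta_e(st), 18)

  st0 <- agent_state(0, 0)
  for (i in 1:18) st0 <- update_ledger(st0, 0, 0)
  st0 <- update_ledger(st0, 1, 0)
  expect_equal(delta_e(st0), 1)

  # warm-up: partial sums over fewer than 18 entries
  stw <- update_ledger(agent_state(0, 0), 5, 2)
  expect_equal(delta_e(stw), 3)

  # brute-force oracle over a random push sequence
  set.seed(4)
  gs <- rnorm(40)
  ls <- rnorm(40)
  st <- agent_state(0, 0)
  for (i in seq_along(gs)) {
    st <- update_ledger(st, gs[i], ls[i])
    lo <- max(1, i - 17)
    expect_equal(delta_e(st), sum(gs[lo:i] - ls[lo:i]))
  }
})

test_that("memory clusters obey the 1600 m switch and running means", {
  cfg <- movement_config()
  st <- agent_state(0, 0, config = cfg)
  st$clusters <- tibble::tibble(cx = 0, cy = 0, n = 1L, order = 1L)
  st$next_order <- 2L

  near <- update_memory(st, c(1599, 0))
  expect_true(near$in_patch)
  far <- update_memory(st, c(1601, 0))
  expect_false(far$in_patch)

  # running-mean centroid update
  upd <- update_memory(st, c(100, 0))
  expect_equal(upd$clusters$cx[1], 50)
  expect_equal(upd$clusters$n[1], 2L)

  # two consecutive out-of-cluster locations found a new cluster
  st2 <- agent_state(0, 0, config = cfg)
  st2 <- update_memory(st2, c(10000, 0))
  expect_false(st2$in_patch)
  expect_equal(nrow(st2$clusters), 0)
  st2 <- update_memory(st2, c(10400, 0))
  expect_true(st2$in_patch)
  expect_equal(nrow(st2$clusters), 1)
  expect_equal(st2$clusters$cx[1], 10200) # midpoint of the founding pair

  # capacity eviction drops the oldest cluster
  cfg3 <- movement_config(memory = list(k_mem = 3))
  st3 <- agent_state(0, 0, config = cfg3)
  for (k in 0:3) {
    st3 <- update_memory(st3, c(k * 10000, 0))
    st3 <- update_memory(st3, c(k * 10000 + 100, 0))
  }
  expect_equal(nrow(st3$clusters), 3)
  expect_false(any(abs(st3$clusters$cx - 50) < 1)) # first cluster evicted
})

test_that("cluster centroids equal the mean of their member locations", {
  set.seed(12)
  cfg <- movement_config(memory = list(k_mem = 50)) # no eviction
  st <- agent_state(0, 0, config = cfg)
  members <- list()
  key_of <- function(loc, keys) {
    # which existing cluster (by recorded members) would absorb loc
    if (!length(keys)) {
      return(NA)
    }
    cent <- vapply(keys, function(k) colMeans(do.call(rbind, members[[k]])),
      numeric(2)
    )
    d <- sqrt(colSums((cent - loc)^2))
    if (min(d) < 1600) keys[which.min(d)] else NA
  }
  pend <- NULL
  for (i in 1:120) {
    loc <- c(runif(1, 0, 20000), runif(1, 0, 20000))
    k <- key_of(loc, seq_along(members))
    if (!is.na(k)) {
      members[[k]] <- c(members[[k]], list(loc))
      pend <- NULL
    } else if (!is.null(pend) && sqrt(sum((pend - loc)^2)) < 1600) {
      members[[length(members) + 1]] <- list(pend, loc)
      pend <- NULL
    } else {
      pend <- loc
    }
    st <- update_memory(st, loc)
  }
  cent <- t(vapply(members, function(m) colMeans(do.call(rbind, m)),
    numeric(2)
  ))
  got <- st$clusters[order(st$clusters$cx), ]
  want <- cent[order(cent[, 1]), , drop = FALSE]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$cx, want[, 1])
  expect_equal(got$cy, want[, 2])
  expect_equal(
    sort(st$clusters$n),
    sort(vapply(members, length, integer(1)))
  )
})

test_that("memory direction term selects the minimum angle", {
  cl <- tibble::tibble(cx = 1000, cy = 0, n = 1L, order = 1L)
  expect_equal(cos_theta_mem(c(0, 0), 0, cl), 1) # dead ahead

  # clusters at 60 and 120 degrees off the bearing -> cos(60) = 0.5
  cl2 <- tibble::tibble(
    cx = cos(c(pi / 3, 2 * pi / 3)) * 1000,
    cy = sin(c(pi / 3, 2 * pi / 3)) * 1000,
    n = 1L, order = 1:2
  )
  expect_equal(cos_theta_mem(c(0, 0), 0, cl2), 0.5)

  expect_equal(cos_theta_mem(c(0, 0), 1.2, cl[0, ]), 0) # empty memory

  # invariance under global rotation of bearing and centroids
  set.seed(3)
  for (i in 1:10) {
    ang <- runif(5, -pi, pi)
    r <- runif(5, 100, 5000)
    b <- runif(1, -pi, pi)
    rot <- runif(1, -pi, pi)
    cl <- tibble::tibble(
      cx = r * cos(ang), cy = r * sin(ang), n = 1L, order = 1:5
    )
    clr <- tibble::tibble(
      cx = r * cos(ang + rot), cy = r * sin(ang + rot), n = 1L, order = 1:5
    )
    expect_equal(
      cos_theta_mem(c(0, 0), b, cl),
      cos_theta_mem(c(0, 0), b + rot, clr)
    )
  }
})

test_that("the disturbance kernel is linear with printed zero-crossings", {
  expect_equal(f_disturbance(0, "road"), 1)
  expect_equal(f_disturbance(1500, "road"), 0)
  expect_equal(f_disturbance(750, "road"), 0.5)
  expect_equal(f_disturbance(1600, "recent_cut"), 0)
  expect_equal(f_disturbance(1300, "regenerating_cut"), 0)
  expect_equal(f_disturbance(1e6, "road"), 0) # clamped at zero
  expect_equal(f_disturbance(Inf, "road"), 0)
  expect_error(f_disturbance(10, "powerline"), "arg")
})
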