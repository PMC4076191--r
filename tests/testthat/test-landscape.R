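test_that("lichen and cover initialise from the class lookup", {
  cfg <- movement_config(landcover = tibble::tibble(
    class = c(3L, 11L), name = c("water", "conifer"),
    lichen = c(0, 60), cover = c(0, 30)
  ))
  g <- landscape_grid(matrix(11L, 3, 3), config = cfg)
  expect_true(all(g$lichen == 60))
  expect_true(all(g$cover == 30))

  mixed <- landscape_grid(matrix(c(3L, 3L, 11L, 11L), 2, 2), config = cfg)
  expect_equal(as.vector(mixed$lichen), c(0, 0, 60, 60))

  expect_error(landscape_grid(matrix(99L, 2, 2)), "unknown landcover class")
})

test_that("point/cell mapping uses half-open 25 m footprints", {
  g <- landscape_grid(matrix(11L, 4, 4), origin = c(100, 200))
  # a point maps to the cell containing it; row 1 is the north row
  expect_equal(point_to_cell(g, 100, 200), cbind(row = 4L, col = 1L))
  expect_equal(point_to_cell(g, 124.999, 200), cbind(row = 4L, col = 1L))
  expect_equal(point_to_cell(g, 125, 200), cbind(row = 4L, col = 2L))
  expect_equal(point_to_cell(g, 100, 299.99), cbind(row = 1L, col = 1L))
  # centre of cell round-trips
  ctr <- cell_center(g, 2, 3)
  expect_equal(point_to_cell(g, ctr[1], ctr[2]), cbind(row = 2L, col = 3L))
  expect_true(in_grid(g, 100, 200))
  expect_false(in_grid(g, 200, 200)) # top/right edges are exclusive
})

test_that("edge operator matches the analytic ramp and the stencil oracle", {
  expect_equal(derive_edge(matrix(50, 6, 6)), matrix(0, 6, 6))

  ramp <- matrix(rep(seq(0, by = 10, length.out = 8), each = 8), 8, 8)
  e <- derive_edge(ramp)
  expect_equal(e[3:6, 3:6], matrix(10, 4, 4)) # 10 %/cell along x only

  chk <- matrix(rep_len(c(0, 100), 49), 7, 7)
  expect_equal(derive_edge(chk), oracle_edge(chk))

  set.seed(51)
  for (i in 1:4) {
    m <- matrix(runif(400, 0, 100), 20, 20)
    expect_equal(derive_edge(m), oracle_edge(m))
  }
  expect_equal(derive_edge(matrix(7, 1, 1)), matrix(0, 1, 1))
})

test_that("ESRI ASCII grids round-trip bit-identically", {
  set.seed(9)
  m <- matrix(sample(1:15, 100 * 100, replace = TRUE), 100, 100)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path, origin = c(5000, -200), cell_size = 25)
  back <- read_ascii_grid(path)
  expect_identical(back$matrix, m + 0) # numeric on re-read
  expect_equal(back$origin, c(5000, -200))
  expect_equal(back$cell_size, 25)

  # load_landscape wires the lookup and edge derivation
  dem <- matrix(runif(1e4, 200, 600), 100, 100)
  dem_path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(dem, dem_path, origin = c(5000, -200), cell_size = 25)
  g <- load_landscape(path, dem_path)
  expect_equal(g$cover_type, matrix(as.integer(m), 100, 100))
  lut <- movement_config()$landcover
  expect_equal(
    g$lichen[1, 1],
    lut$lichen[match(m[1, 1], lut$class)]
  )
  expect_equal(g$altitude, dem, tolerance = 1e-6)
})

test_that("nearest-feature distance and angle match the exhaustive oracle", {
  w <- road_world(n = 30, road_col = 15)
  # on the road itself
  on_road <- cell_center(w$grid, 10, 15)
  da <- distance_angle_to_feature(on_road, 0, w$features, "road")
  expect_equal(da$distance, 0)

  # road cell due north, heading due north (+y)
  g <- landscape_grid(matrix(11L, 80, 80))
  road <- matrix(FALSE, 80, 80)
  start <- cell_center(g, 60, 40)
  north_rc <- point_to_cell(g, start[1], start[2] + 1000)
  road[north_rc] <- TRUE
  f <- feature_layers(g, road = road)
  da <- distance_angle_to_feature(start, pi / 2, f, "road")
  expect_equal(da$distance, 1000)
  expect_equal(da$cos_theta, 1)

  # random masks vs exhaustive scan
  set.seed(77)
  for (i in 1:3) {
    n <- 40
    mask <- matrix(runif(n * n) < 0.02, n, n)
    if (!any(mask)) mask[5, 7] <- TRUE
    gg <- landscape_grid(matrix(11L, n, n))
    ff <- feature_layers(gg, road = mask)
    pt <- c(runif(1, 0, n * 25), runif(1, 0, n * 25))
    got <- distance_angle_to_feature(pt, 0.3, ff, "road")
    want <- oracle_nearest_feature(pt, mask, c(0, 0), 25)
    if (got$distance > 0) {
      expect_equal(got$distance, want$distance)
      ang <- atan2(want$xy[2] - pt[2], want$xy[1] - pt[1])
      expect_equal(got$cos_theta, cos(ang - 0.3))
    }
  }

  # absent feature kind
  empty <- feature_layers(g)
  da <- distance_angle_to_feature(c(10, 10), 0, empty, "recent_cut")
  expect_equal(da$distance, Inf)
  expect_equal(da$cos_theta, 0)
  expect_error(
    distance_angle_to_feature(c(0, 0), 0, f, "powerline"),
    "arg"
  )
})

test_that("encroachment converts 70% of a clean quadrat and spares water", {
  cfg <- movement_config()
  # one full 15 km x 15 km quadrat with no protected cells
  g <- landscape_grid(matrix(11L, 600, 600), config = cfg)
  out <- apply_encroachment(g)
  frac <- mean(out$cover_type == 12L)
  expect_lt(abs(frac - 0.70), 0.01)
  expect_equal(dim(out$cover_type), dim(g$cover_type))
  # converted cells get the target class attributes
  lut <- cfg$landcover
  expect_equal(
    out$lichen[300, 300],
    lut$lichen[lut$class == 12L]
  )
  # corner cells (outside the centred square) untouched
  expect_equal(out$cover_type[1, 1], 11L)
  expect_equal(out$lichen[1, 1], g$lichen[1, 1])

  # water at the quadrat centre is protected
  ct <- matrix(11L, 600, 600)
  ct[300, 300] <- 3L
  g2 <- landscape_grid(ct, config = cfg)
  out2 <- apply_encroachment(g2)
  expect_equal(out2$cover_type[300, 300], 3L)

  expect_error(scenario_spec(converted_fraction = 0), "converted_fraction")
  expect_error(scenario_spec(converted_fraction = 1.2), "converted_fraction")
})

test_that("yearly update ages recent cuts into regenerating cuts", {
  g <- landscape_grid(matrix(11L, 10, 10))
  age <- matrix(NA_integer_, 10, 10)
  age[2, 2] <- 4L # one increment away from the 5-year mark
  age[3, 3] <- 3L
  f <- feature_layers(g, recent_cut_age = age)

  f1 <- advance_year(f)
  expect_true(f1$regenerating_cut[2, 2])
  expect_true(is.na(f1$recent_cut_age[2, 2]))
  expect_false(f1$regenerating_cut[3, 3])
  expect_equal(f1$recent_cut_age[3, 3], 4L)

  # a cut already at age 5 is reclassified on the next update
  age5 <- matrix(NA_integer_, 10, 10)
  age5[4, 4] <- 5L
  f5 <- advance_year(feature_layers(g, recent_cut_age = age5))
  expect_true(f5$regenerating_cut[4, 4])

  # total cut footprint is non-decreasing over years without new cuts
  tot <- function(ff) sum(!is.na(ff$recent_cut_age)) + sum(ff$regenerating_cut)
  ff <- f
  prev <- tot(ff)
  for (y in 1:7) {
    ff <- advance_year(ff)
    expect_gte(tot(ff), prev)
    prev <- tot(ff)
  }
  # new cuts enter at age 0
  nc <- matrix(FALSE, 10, 10)
  nc[9, 9] <- TRUE
  f2 <- advance_year(f, new_cuts = nc)
  expect_equal(f2$recent_cut_age[9, 9], 0L)
})

test_that("synthetic landscapes are seeded and respect the class mixture", {
  a <- synth_landscape(seed = 42, nrows = 50, ncols = 50)
  b <- synth_landscape(seed = 42, nrows = 50, ncols = 50)
  expect_identical(a$grid$cover_type, b$grid$cover_type)
  expect_identical(a$grid$altitude, b$grid$altitude)
  expect_identical(a$features$road, b$features$road)

  solo <- synth_landscape(
    seed = 1, nrows = 30, ncols = 30,
    class_mixture = c("11" = 1), n_roads = 0, n_cuts = 0
  )
  expect_true(all(solo$grid$cover_type == 11L))

  mix <- c("11" = 0.5, "10" = 0.3, "5" = 0.2)
  big <- synth_landscape(
    seed = 3, nrows = 500, ncols = 500,
    class_mixture = mix, n_roads = 0, n_cuts = 0
  )
  freq <- table(big$grid$cover_type) / length(big$grid$cover_type)
  expect_true(all(abs(freq[names(mix)] - mix) < 0.03))

  expect_error(
    synth_landscape(seed = 1, class_mixture = c("11" = 1.2, "10" = -0.2)),
    "negative"
  )
})
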