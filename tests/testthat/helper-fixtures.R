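# Small worlds and tracks built in code for the tests.

# uniform single-class landscape with empty feature layers
flat_world <- function(n = 40, class = 11L, altitude = 300,
                       config = movement_config()) {
  grid <- landscape_grid(matrix(class, n, n),
    altitude = altitude,
    config = config
  )
  list(grid = grid, features = feature_layers(grid), config = config)
}

# a vertical road in the given column of an otherwise uniform landscape
road_world <- function(n = 40, road_col = 20, class = 11L,
                       config = movement_config()) {
  ct <- matrix(class, n, n)
  ct[, road_col] <- 15L
  grid <- landscape_grid(ct, config = config)
  road <- matrix(FALSE, n, n)
  road[, road_col] <- TRUE
  list(
    grid = grid, features = feature_layers(grid, road = road),
    config = config
  )
}

# build a track tibble from a coordinate matrix at the nominal interval
make_track <- function(xy, id = "a",
                       start = as.POSIXct("2009-01-05 00:00:00", tz = "UTC"),
                       interval_h = 4) {
  tibble::tibble(
    id = id,
    t = start + (seq_len(nrow(xy)) - 1) * interval_h * 3600,
    x = xy[, 1], y = xy[, 2]
  )
}

# degenerate distributions for deterministic candidate geometry
fixed_distros <- function(sl = 100, ta = 0) {
  structure(list(sl = sl, ta = ta), class = "empirical_distros")
}

# a small replayed covariate table on a synthetic world (cached per session)
demo_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      land <- synth_landscape(seed = 402, nrows = 120, ncols = 120)
      tr <- synth_tracks(
        n_individuals = 3, n_fixes = 70, start = c(1500, 1500), seed = 403
      )
      di <- empirical_distributions(decompose_steps(tr))
      set.seed(404)
      cache <<- suppressWarnings(
        replay_tracks(tr, land$grid, land$features, di)
      )$table
    }
    cache
  }
})
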