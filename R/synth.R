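#' Synthetic landscape generator
#'
#' Builds a seeded, reproducible winter landscape: a spatially autocorrelated
#' landcover mosaic (classes drawn at a coarse patch scale from the requested
#' mixture, then disaggregated to 25 m cells), a smoothed-noise DEM, linear
#' road features, and rectangular recent/regenerating cut blocks. Landcover
#' classes and the feature masks are kept consistent (road cells get class
#' 15, recent cuts class 14, regenerating cuts class 13).
#'
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param nrows,ncols grid dimensions in cells.
#' @param class_mixture named numeric vector of class frequencies (names are
#'   class codes); must be non-negative and sum to 1.
#' @param patchiness expected landcover patch size in cells (coarse block
#'   edge = `round(sqrt(patchiness))`).
#' @param n_roads number of straight roads crossing the map.
#' @param n_cuts number of rectangular cut blocks (split between recent and
#'   regenerating).
#' @param relief approximate DEM amplitude in metres.
#' @param config a [movement_config()].
#' @return A list with elements `grid` ([landscape_grid()]) and `features`
#'   ([feature_layers()]).
#' @export
#' @examples
#' land <- synth_landscape(seed = 1, nrows = 60, ncols = 60)
#' table(land$grid$cover_type)[1:3]
synth_landscape <- function(seed, nrows = 200, ncols = 200,
                            class_mixture = c(
                              "11" = 0.35, "10" = 0.2, "9" = 0.15, "5" = 0.1,
                              "12" = 0.1, "6" = 0.05, "3" = 0.03, "1" = 0.02
                            ),
                            patchiness = 25, n_roads = 2, n_cuts = 4,
                            relief = 300, config = movement_config()) {
  if (any(class_mixture < 0)) stop("negative mixture weights", call. = FALSE)
  if (abs(sum(class_mixture) - 1) > 1e-6) {
    stop("class_mixture must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  classes <- as.integer(names(class_mixture))

  # landcover: iid classes on a coarse grid, disaggregated to cell scale
  blk <- max(1L, as.integer(round(sqrt(patchiness))))
  cnr <- ceiling(nrows / blk)
  cnc <- ceiling(ncols / blk)
  coarse <- matrix(
    classes[sample.int(length(classes), cnr * cnc,
      replace = TRUE, prob = class_mixture
    )],
    cnr, cnc
  )
  cover_type <- coarse[
    rep(seq_len(cnr), each = blk)[seq_len(nrows)],
    rep(seq_len(cnc), each = blk)[seq_len(ncols)]
  ]

  # DEM: coarse gaussian noise, disaggregated then mean-filtered
  dem_coarse <- matrix(stats::rnorm(cnr * cnc, 400, relief / 3), cnr, cnc)
  altitude <- dem_coarse[
    rep(seq_len(cnr), each = blk)[seq_len(nrows)],
    rep(seq_len(cnc), each = blk)[seq_len(ncols)]
  ]
  for (i in 1:3) altitude <- mean_filter3(altitude)

  # roads: straight lines with random orientation and offset
  road <- matrix(FALSE, nrows, ncols)
  if (n_roads > 0) {
    for (k in seq_len(n_roads)) {
      theta <- stats::runif(1, 0, pi)
      r0 <- stats::runif(1, 1, nrows)
      c0 <- stats::runif(1, 1, ncols)
      tt <- seq(-max(nrows, ncols), max(nrows, ncols), by = 0.5)
      rr <- round(r0 + tt * sin(theta))
      cc <- round(c0 + tt * cos(theta))
      ok <- rr >= 1 & rr <= nrows & cc >= 1 & cc <= ncols
      road[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  cover_type[road] <- 15L

  # cut blocks: axis-aligned rectangles, half recent, half regenerating
  rc_age <- matrix(NA_integer_, nrows, ncols)
  regen <- matrix(FALSE, nrows, ncols)
  if (n_cuts > 0) {
    for (k in seq_len(n_cuts)) {
      h <- sample(3:max(3, nrows %/% 12), 1)
      w <- sample(3:max(3, ncols %/% 12), 1)
      r0 <- sample(seq_len(max(1, nrows - h)), 1)
      c0 <- sample(seq_len(max(1, ncols - w)), 1)
      cells <- cbind(
        rep(r0:(r0 + h - 1), w),
        rep(c0:(c0 + w - 1), each = h)
      )
      cells <- cells[!road[cells], , drop = FALSE]
      if (k %% 2 == 1) {
        rc_age[cells] <- sample(0:4, 1)
        cover_type[cells] <- 14L
      } else {
        regen[cells] <- TRUE
        cover_type[cells] <- 13L
      }
    }
  }

  grid <- landscape_grid(cover_type,
    altitude = altitude,
    cell_size = config$cell_size, config = config
  )
  features <- feature_layers(grid,
    road = road, recent_cut_age = rc_age,
    regenerating_cut = regen, burned = grid$cover_type == 2L
  )
  list(grid = grid, features = features)
}

# 3x3 mean filter with replicate padding
mean_filter3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  up <- m[c(1, 1:(nr - 1)), , drop = FALSE]
  dn <- m[c(2:nr, nr), , drop = FALSE]
  v <- (up + m + dn) / 3
  lf <- v[, c(1, 1:(nc - 1)), drop = FALSE]
  rt <- v[, c(2:nc, nc), drop = FALSE]
  (lf + v + rt) / 3
}

#' Synthetic GPS tracks
#'
#' Generates correlated-random-walk tracks at the nominal 4 h fix interval,
#' for seeding demonstrations and tests: step lengths are gamma distributed
#' and turning angles wrapped-normal around zero (persistent headings).
#' Fixes start at the beginning of the winter window.
#'
#' @param n_individuals number of tracks.
#' @param n_fixes fixes per track.
#' @param start numeric length-2 or matrix of start coordinates (m), one row
#'   per individual (recycled).
#' @param sl_mean,sl_shape mean (m) and gamma shape of step lengths.
#' @param ta_sd circular concentration of turning angles (radians).
#' @param start_time POSIXct of the first fix.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param config a [movement_config()].
#' @return A track tibble with columns `id`, `t`, `x`, `y`.
#' @export
synth_tracks <- function(n_individuals = 3, n_fixes = 100, start = c(0, 0),
                         sl_mean = 300, sl_shape = 1.5, ta_sd = 0.8,
                         start_time = as.POSIXct("2008-12-28 00:00:00",
                           tz = "UTC"
                         ),
                         seed = NULL, config = movement_config()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(start))) start <- matrix(start, 1, 2)
  dt <- config$winter$fix_interval_hours * 3600
  out <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    s0 <- start[(i - 1) %% nrow(start) + 1, ]
    x <- numeric(n_fixes)
    y <- numeric(n_fixes)
    x[1] <- s0[1]
    y[1] <- s0[2]
    h <- stats::runif(1, -pi, pi)
    for (k in 2:n_fixes) {
      h <- wrap_pi(h + stats::rnorm(1, 0, ta_sd))
      sl <- stats::rgamma(1, shape = sl_shape, scale = sl_mean / sl_shape)
      x[k] <- x[k - 1] + sl * cos(h)
      y[k] <- y[k - 1] + sl * sin(h)
    }
    out[[i]] <- tibble::tibble(
      id = paste0("ind", i),
      t = start_time + dt * (seq_len(n_fixes) - 1),
      x = x, y = y
    )
  }
  dplyr::bind_rows(out)
}
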