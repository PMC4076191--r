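# The surrogate-data engine: replays observed tracks through the energetics,
# memory and disturbance submodels to emit the SSF covariate table.

ssf_covariate_names <- function() {
  c(
    "cos_t_mem", "g_over_l", "cover", "altitude", "edge",
    "road_term", "recent_cut_term", "regen_cut_term",
    "gl_x_de", "cover_x_de"
  )
}

#' Covariates of candidate steps
#'
#' Computes the full SSF covariate vector for one or more candidate steps
#' sharing a start point, given the agent state at decision time. End-of-step
#' attributes (`cover`, `altitude`, `edge`) come from the end cell; the
#' hypothetical gain `G` from the end cell's current biomass (no depletion);
#' `L` from the step length and altitude difference; the three disturbance
#' terms are `cos(theta_kind) * f(D_kind)` with distance and feature
#' direction measured from the shared start; and the interactions use the
#' ledger sum at decision time (scaled by `delta_e_scale`).
#'
#' @param state an [agent_state()] (position = shared start).
#' @param candidates a tibble of candidate steps (`sl`, `bearing`, `x1`,
#'   `y1`) as from [draw_random_steps()]; ends must lie inside the grid.
#' @param grid a [landscape_grid()].
#' @param features a [feature_layers()].
#' @return A tibble, one row per candidate, with the 10 SSF covariates plus
#'   bookkeeping columns `g_raw`, `l_raw`, `de`.
#' @export
covariates_for_step <- function(state, candidates, grid, features) {
  cfg <- state$config
  en <- cfg$energetics
  start <- c(state$x, state$y)
  if (!all(in_grid(grid, candidates$x1, candidates$y1))) {
    stop("candidate end outside grid", call. = FALSE)
  }

  v_end <- grid_value(grid, "lichen", candidates$x1, candidates$y1)
  cover <- grid_value(grid, "cover", candidates$x1, candidates$y1)
  alt1 <- grid_value(grid, "altitude", candidates$x1, candidates$y1)
  edge <- grid_value(grid, "edge", candidates$x1, candidates$y1)
  alt0 <- grid_value(grid, "altitude", start[1], start[2])

  G <- gain(intake(v_end, en$a, en$b),
    body_mass = en$body_mass,
    step_hours = cfg$winter$fix_interval_hours,
    gain_kj_per_g = en$gain_kj_per_g
  )$G
  L <- loss(candidates$sl,
    dalt = alt1 - alt0, bmr_per_step = en$bmr_per_step,
    c_dist = en$c_dist, c_climb = en$c_climb
  )
  de <- delta_e(state) * en$delta_e_scale

  dist_term <- function(kind) {
    da <- distance_angle_to_feature(start, 0, features, kind)
    if (!is.finite(da$distance)) {
      return(rep(0, nrow(candidates)))
    }
    f <- f_disturbance(da$distance, kind, cfg)
    if (da$distance == 0) {
      return(rep(f, nrow(candidates))) # cos := 1 inside the feature cell
    }
    # direction to the nearest feature from the shared start:
    ctr <- features$centers[[kind]]
    dx <- ctr[, 1] - start[1]
    dy <- ctr[, 2] - start[2]
    i <- which.min(dx * dx + dy * dy)
    theta <- atan2(dy[i], dx[i])
    cos(wrap_pi(candidates$bearing - theta)) * f
  }

  gl <- G / L
  n <- nrow(candidates)
  tibble::new_tibble(list(
    cos_t_mem = cos_theta_mem(start, candidates$bearing, state$clusters),
    g_over_l = gl,
    cover = cover,
    altitude = alt1,
    edge = edge,
    road_term = dist_term("road"),
    recent_cut_term = dist_term("recent_cut"),
    regen_cut_term = dist_term("regenerating_cut"),
    gl_x_de = gl * de,
    cover_x_de = cover * de,
    g_raw = G, l_raw = L, de = rep(de, n)
  ), nrow = n)
}

# draw n candidates whose ends are inside the grid (and optionally a
# confinement polygon), redrawing failures up to max_redraws times; failures
# after the cap are kept in place (sl = 0)
draw_valid_candidates <- function(start, heading, distros, n, grid,
                                  polygon = NULL, max_redraws = 100) {
  cand <- draw_random_steps(start, heading, distros, n)
  ok <- in_grid(grid, cand$x1, cand$y1)
  if (!is.null(polygon)) {
    ok <- ok & point_in_polygon(cand$x1, cand$y1, polygon)
  }
  tries <- 0
  while (any(!ok) && tries < max_redraws) {
    redo <- which(!ok)
    cand[redo, ] <- draw_random_steps(start, heading, distros, length(redo))
    ok[redo] <- in_grid(grid, cand$x1[redo], cand$y1[redo])
    if (!is.null(polygon)) {
      ok[redo] <- ok[redo] &
        point_in_polygon(cand$x1[redo], cand$y1[redo], polygon)
    }
    tries <- tries + 1
  }
  if (any(!ok)) {
    redo <- which(!ok)
    cand$sl[redo] <- 0
    cand$x1[redo] <- start[1]
    cand$y1[redo] <- start[2]
    attr(cand, "exhausted") <- length(redo)
  }
  cand
}

#' Replay an observed track through the submodels
#'
#' The surrogate-data generator: iterates an individual's observed steps in
#' order and, for each step with a defined previous heading, records a
#' stratum of 1 observed plus `n_random` random candidate steps with all SSF
#' covariates evaluated at the current internal state. Only the observed
#' step then mutates state: the animal feeds at the step end (depleting the
#' cell's lichen, capped at what the cell holds), pushes `G - L` onto the
#' energy ledger, updates the memory clusters with the end location, and
#' takes the observed bearing as its new heading. Random candidates never
#' change state.
#'
#' Strata whose observed end leaves the grid are skipped with a warning.
#' Random candidates falling off the grid are redrawn (up to the configured
#' cap) so every stratum keeps its full control set.
#'
#' @param track a track tibble for one individual, or a pre-computed step
#'   tibble from [decompose_steps()].
#' @param grid a [landscape_grid()]; its lichen layer is depleted in the
#'   returned copy.
#' @param features a [feature_layers()].
#' @param distros an [empirical_distributions()] object.
#' @param config a [movement_config()].
#' @param window passed to [decompose_steps()] when `track` is raw fixes.
#' @return A list with `table` (the covariate tibble: `stratum`, `id`, `t`,
#'   `case`, step geometry, the 10 covariates, `g_raw`, `l_raw`, `de`,
#'   `ingested_g` for the applied observed steps), `grid` (the depleted
#'   landscape) and `total_ingested_g`. Heading-seeding steps (the first of
#'   each track segment) feed without forming a stratum, so
#'   `total_ingested_g` can slightly exceed the sum of `ingested_g` over
#'   the table.
#' @export
replay_track <- function(track, grid, features, distros,
                         config = movement_config(), window = FALSE) {
  steps <- if (all(c("sl", "bearing") %in% names(track))) {
    track
  } else {
    decompose_steps(track, window = window, config = config)
  }
  if (length(unique(steps$id)) > 1) {
    stop("replay_track() replays one individual; split tracks first",
      call. = FALSE
    )
  }
  en <- config$energetics
  cell_area <- grid$cell_size^2
  state <- agent_state(steps$x0[1], steps$y0[1],
    heading = steps$bearing[1],
    id = steps$id[1], config = config
  )
  rows <- vector("list", nrow(steps))
  skipped <- 0L
  total_ing <- 0

  for (k in seq_len(nrow(steps))) {
    stp <- steps[k, ]
    state$x <- stp$x0
    state$y <- stp$y0
    has_heading <- !is.na(stp$ta)
    if (has_heading) {
      heading <- wrap_pi(stp$bearing - stp$ta) # previous step's bearing
    } else {
      heading <- stp$bearing # segment start: seeds the heading only
    }
    state$heading <- heading

    if (!in_grid(grid, stp$x1, stp$y1) || !in_grid(grid, stp$x0, stp$y0)) {
      skipped <- skipped + 1L
    } else if (has_heading) {
      obs <- tibble::tibble(
        sl = stp$sl, ta = stp$ta, bearing = stp$bearing,
        x0 = stp$x0, y0 = stp$y0, x1 = stp$x1, y1 = stp$y1
      )
      rnd <- draw_valid_candidates(
        c(stp$x0, stp$y0), heading, distros, config$ssf$n_random, grid,
        max_redraws = config$simulation$max_redraws
      )
      cand <- dplyr::bind_rows(obs, rnd)
      cov <- covariates_for_step(state, cand, grid, features)
      nr <- nrow(cand)
      rows[[k]] <- tibble::new_tibble(
        c(
          list(
            stratum = rep(paste0(stp$id, "_", k), nr),
            id = rep(stp$id, nr), t = rep(stp$t1, nr),
            case = c(1L, rep(0L, nr - 1L))
          ),
          as.list(cand), as.list(cov)
        ),
        nrow = nr
      )
    }

    # apply the observed step (even when it could not form a stratum)
    if (in_grid(grid, stp$x1, stp$y1)) {
      rc <- point_to_cell(grid, stp$x1, stp$y1)
      v <- grid$lichen[rc]
      fed <- gain(intake(v, en$a, en$b),
        body_mass = en$body_mass,
        step_hours = config$winter$fix_interval_hours,
        gain_kj_per_g = en$gain_kj_per_g,
        available_g = v * cell_area
      )
      grid$lichen[rc] <- max(0, v - fed$ingested_g / cell_area)
      total_ing <- total_ing + fed$ingested_g
      alt0 <- if (in_grid(grid, stp$x0, stp$y0)) {
        grid_value(grid, "altitude", stp$x0, stp$y0)
      } else {
        grid_value(grid, "altitude", stp$x1, stp$y1)
      }
      L <- loss(stp$sl,
        dalt = grid_value(grid, "altitude", stp$x1, stp$y1) - alt0,
        bmr_per_step = en$bmr_per_step, c_dist = en$c_dist,
        c_climb = en$c_climb
      )
      state <- update_ledger(state, fed$G, L)
      state <- update_memory(state, c(stp$x1, stp$y1))
      if (!is.null(rows[[k]])) {
        rows[[k]]$ingested_g <- c(fed$ingested_g, rep(0, nrow(rows[[k]]) - 1))
      }
    }
    state$heading <- stp$bearing
  }

  if (skipped > 0) {
    warning(skipped, " stratum/strata skipped: track leaves the grid",
      call. = FALSE
    )
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) > 0 && !"ingested_g" %in% names(tab)) tab$ingested_g <- 0
  list(table = tab, grid = grid, total_ingested_g = total_ing)
}

#' Replay several individuals
#'
#' Applies [replay_track()] to each individual in turn on a shared landscape
#' (so depletion by earlier individuals is seen by later ones, in id order).
#'
#' @inheritParams replay_track
#' @param tracks a track tibble with one or more individuals.
#' @return As [replay_track()]: `table` across individuals plus the
#'   depleted `grid`.
#' @export
replay_tracks <- function(tracks, grid, features, distros,
                          config = movement_config(), window = FALSE) {
  ids <- unique(tracks$id)
  tabs <- vector("list", length(ids))
  total <- 0
  for (i in seq_along(ids)) {
    r <- replay_track(tracks[tracks$id == ids[i], ], grid, features, distros,
      config = config, window = window
    )
    tabs[[i]] <- r$table
    grid <- r$grid
    total <- total + r$total_ingested_g
  }
  list(
    table = dplyr::bind_rows(tabs), grid = grid,
    total_ingested_g = total
  )
}

#' Read / write a covariate table
#'
#' Tidy CSV persistence for the stratified SSF input table.
#'
#' @param table a covariate tibble from [replay_track()].
#' @param path CSV path.
#' @return `read_covariate_table()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_covariate_table <- function(table, path) {
  out <- table
  if ("t" %in% names(out)) {
    out$t <- format(out$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariate_table
#' @export
read_covariate_table <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("t" %in% names(df)) {
    df$t <- as.POSIXct(df$t, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  }
  df
}
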