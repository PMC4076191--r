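# The forward individual-based model: a biased correlated random walk whose
# per-step bias is the fitted SSF score over a drawn candidate set.

#' Score candidate steps with a fitted SSF
#'
#' `w_i = exp(beta' x_i)` over the covariate rows of the candidates;
#' strictly positive.
#'
#' @param cov covariate tibble from [covariates_for_step()].
#' @param beta named coefficient vector (or an [fit_clogit()] object).
#' @return numeric vector of scores.
#' @export
score_candidates <- function(cov, beta) {
  if (inherits(beta, "ssf_fit")) beta <- beta$coefficients
  X <- as.matrix(cov[names(beta)])
  exp(as.vector(X %*% beta))
}

#' Select a step from scored candidates
#'
#' The selection rules:
#' \describe{
#'   \item{best}{always the highest score (ties broken by a seeded shuffle).}
#'   \item{best90}{the highest score with probability `best90_p` (0.9);
#'     otherwise any candidate uniformly (including the best).}
#'   \item{roulette}{probability proportional to the logistic transform
#'     `w/(1+w)`, normalised over the candidate set.}
#'   \item{ssf}{probability proportional to the raw score `w` - the exact
#'     sampler of the conditional-logit model, used for parameter-recovery
#'     checks.}
#'   \item{crw}{uniform over candidates (the null model).}
#' }
#'
#' @param scores positive scores from [score_candidates()].
#' @param method one of `"best"`, `"best90"`, `"roulette"`, `"ssf"`,
#'   `"crw"`.
#' @param best90_p exploit probability of best90.
#' @return the selected candidate index.
#' @export
select_step <- function(scores, method = "best90", best90_p = 0.9) {
  n <- length(scores)
  if (n == 0) stop("empty score vector", call. = FALSE)
  method <- match.arg(method, c("best", "best90", "roulette", "ssf", "crw"))
  argmax_shuffled <- function() {
    ord <- sample.int(n)
    ord[which.max(scores[ord])]
  }
  switch(method,
    best = argmax_shuffled(),
    best90 = if (stats::runif(1) < best90_p) {
      argmax_shuffled()
    } else {
      sample.int(n, 1)
    },
    roulette = {
      p <- (scores / (1 + scores))
      sample.int(n, 1, prob = p / sum(p))
    },
    ssf = sample.int(n, 1, prob = scores / sum(scores)),
    crw = sample.int(n, 1)
  )
}

#' Point-in-polygon test
#'
#' @param x,y point coordinates (vectorized).
#' @param polygon two-column matrix of vertices (closed implicitly).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, polygon) {
  mgcv::in.out(as.matrix(polygon), cbind(x, y))
}

#' Simulate SSF-driven movement
#'
#' Runs the scheduled biased correlated random walk: at every iteration,
#' each individual in fixed id order draws its candidate steps from the
#' empirical step-length/turning-angle distributions (out-of-map candidates
#' redrawn; optional confinement polygons enforced by rejection), scores
#' them with the SSF, selects one by the chosen rule, moves, feeds at the
#' new cell (gain capped by the cell's lichen, which is depleted), pushes
#' `G - L` onto its energy ledger, and updates its memory clusters and
#' heading. Depletion makes the order of individuals within an iteration
#' matter; the order is fixed and the run is reproducible under a seed.
#'
#' @param grid a [landscape_grid()].
#' @param features a [feature_layers()].
#' @param beta named SSF coefficient vector or an [fit_clogit()] object.
#' @param distros an [empirical_distributions()] object.
#' @param n_individuals number of agents.
#' @param n_iterations steps per agent; defaults to one winter season
#'   ([winter_step_count()]).
#' @param method selection rule, see [select_step()].
#' @param init start coordinates: a matrix with one row per individual, a
#'   single (x, y), or `NULL` to start agents at random cells of
#'   `init_class`.
#' @param init_class landcover class for random initialisation (default 11,
#'   lichen-rich open conifer).
#' @param confinement optional list of per-individual polygons (two-column
#'   matrices); candidate ends are kept inside by redraw.
#' @param seed RNG seed or `NULL`.
#' @param start_time POSIXct stamped on the first fix.
#' @param config a [movement_config()].
#' @return A list of class `ssf_simulation`: `tracks` (tibble `id`, `t`,
#'   `x`, `y`), `step_log` (one row per candidate per step: covariates,
#'   `score`, `chosen`, `ingested_g` on chosen rows), `grid` (depleted),
#'   `total_ingested_g` per individual.
#' @export
simulate_movement <- function(grid, features, beta, distros,
                              n_individuals = 5,
                              n_iterations = winter_step_count(config),
                              method = config$simulation$selection,
                              init = NULL, init_class = 11L, confinement = NULL,
                              seed = NULL,
                              start_time = as.POSIXct("2008-12-28 00:00:00",
                                tz = "UTC"
                              ),
                              config = movement_config()) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(beta, "ssf_fit")) beta <- beta$coefficients
  stopifnot(n_iterations >= 1)
  en <- config$energetics
  cell_area <- grid$cell_size^2
  m <- n_candidates(config)
  dt <- config$winter$fix_interval_hours * 3600

  if (is.null(init)) {
    cells <- which(grid$cover_type == init_class, arr.ind = TRUE)
    if (nrow(cells) == 0) cells <- which(grid$cover_type > 0, arr.ind = TRUE)
    pick <- cells[sample.int(nrow(cells), n_individuals, replace = TRUE), ,
      drop = FALSE
    ]
    init <- cell_center(grid, pick[, 1], pick[, 2])
  } else if (is.null(dim(init))) {
    init <- matrix(init, n_individuals, 2, byrow = TRUE)
  }

  ids <- sprintf("sim%02d", seq_len(n_individuals))
  states <- lapply(seq_len(n_individuals), function(i) {
    st <- agent_state(init[(i - 1) %% nrow(init) + 1, 1],
      init[(i - 1) %% nrow(init) + 1, 2],
      heading = stats::runif(1, -pi, pi), id = ids[i], config = config
    )
    st
  })
  total_ing <- stats::setNames(numeric(n_individuals), ids)

  fix_rows <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    fix_rows[[i]] <- matrix(NA_real_, n_iterations + 1, 2)
    fix_rows[[i]][1, ] <- c(states[[i]]$x, states[[i]]$y)
  }
  log_rows <- vector("list", n_iterations * n_individuals)
  li <- 0L

  for (it in seq_len(n_iterations)) {
    for (i in seq_len(n_individuals)) {
      st <- states[[i]]
      start <- c(st$x, st$y)
      poly <- if (!is.null(confinement)) confinement[[(i - 1) %% length(confinement) + 1]]
      cand <- draw_valid_candidates(start, st$heading, distros, m, grid,
        polygon = poly, max_redraws = config$simulation$max_redraws
      )
      cov <- covariates_for_step(st, cand, grid, features)
      scores <- score_candidates(cov, beta)
      j <- select_step(scores, method, config$simulation$best90_p)

      # move and feed
      rc <- point_to_cell(grid, cand$x1[j], cand$y1[j])
      v <- grid$lichen[rc]
      fed <- gain(intake(v, en$a, en$b),
        body_mass = en$body_mass,
        step_hours = config$winter$fix_interval_hours,
        gain_kj_per_g = en$gain_kj_per_g, available_g = v * cell_area
      )
      grid$lichen[rc] <- max(0, v - fed$ingested_g / cell_area)
      total_ing[i] <- total_ing[i] + fed$ingested_g
      st <- update_ledger(st, fed$G, cov$l_raw[j])
      st <- update_memory(st, c(cand$x1[j], cand$y1[j]))
      st$x <- cand$x1[j]
      st$y <- cand$y1[j]
      st$heading <- cand$bearing[j]
      states[[i]] <- st
      fix_rows[[i]][it + 1, ] <- c(st$x, st$y)

      li <- li + 1L
      log_rows[[li]] <- tibble::new_tibble(
        c(
          list(
            stratum = rep(paste0(ids[i], "_", it), m),
            id = rep(ids[i], m),
            t = rep(start_time + it * dt, m),
            chosen = seq_len(m) == j,
            case = as.integer(seq_len(m) == j)
          ),
          as.list(cand), as.list(cov),
          list(
            score = scores,
            ingested_g = ifelse(seq_len(m) == j, fed$ingested_g, 0)
          )
        ),
        nrow = m
      )
    }
  }

  tracks <- dplyr::bind_rows(lapply(seq_len(n_individuals), function(i) {
    tibble::tibble(
      id = ids[i],
      t = start_time + dt * (0:n_iterations),
      x = fix_rows[[i]][, 1], y = fix_rows[[i]][, 2]
    )
  }))
  structure(
    list(
      tracks = tracks, step_log = dplyr::bind_rows(log_rows),
      grid = grid, total_ingested_g = total_ing,
      method = method, n_iterations = n_iterations
    ),
    class = "ssf_simulation"
  )
}

#' @export
print.ssf_simulation <- function(x, ...) {
  cat(
    "<ssf_simulation>", length(unique(x$tracks$id)), "individuals x",
    x$n_iterations, "steps, selection:", x$method, "\n"
  )
  invisible(x)
}

#' Confine a candidate step to a polygon
#'
#' Redraws a candidate until its end point falls inside the polygon (start
#' point unchanged); after `cap` failed redraws the shortest draw seen is
#' retained and flagged.
#'
#' @param candidate one-row candidate tibble (from [draw_random_steps()]).
#' @param polygon two-column vertex matrix; the start must lie inside.
#' @param distros an [empirical_distributions()] object.
#' @param heading current heading (radians).
#' @param cap redraw cap (default 1000).
#' @return A one-row candidate tibble; attribute `"capped"` is `TRUE` when
#'   the cap was reached.
#' @export
confine <- function(candidate, polygon, distros, heading, cap = 1000) {
  start <- c(candidate$x0[1], candidate$y0[1])
  if (!point_in_polygon(start[1], start[2], polygon)) {
    stop("start point outside the confinement polygon", call. = FALSE)
  }
  if (point_in_polygon(candidate$x1[1], candidate$y1[1], polygon)) {
    return(candidate)
  }
  best <- candidate
  for (k in seq_len(cap)) {
    cand <- draw_random_steps(start, heading, distros, 1)
    if (point_in_polygon(cand$x1[1], cand$y1[1], polygon)) {
      return(cand)
    }
    if (cand$sl < best$sl) best <- cand
  }
  attr(best, "capped") <- TRUE
  best
}
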