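#' Michaelis-Menten forage intake
#'
#' Short-term functional response of lichen consumption:
#' `X = a V / (b + V)`, monotone increasing and concave in the cell biomass
#' `V`, saturating at the maximum rate `a`. At `V = b` intake is half of
#' `a`.
#'
#' @param V resource biomass of the cell, g/m2 (vectorized, must be >= 0).
#' @param a maximum consumption rate, g/day per kg body mass (default 61.3).
#' @param b biomass at half-maximal intake, g/m2 (default 40).
#' @return intake rate X, g/day per kg body mass.
#' @export
#' @examples
#' intake(40) # half of 61.3
intake <- function(V, a = 61.3, b = 40) {
  if (any(V < 0)) stop("biomass V must be non-negative", call. = FALSE)
  a * V / (b + V)
}

#' Energy gain of a step
#'
#' Converts the intake rate at the step-end cell into a per-step energy gain:
#' grams ingested = `X * body_mass * step_hours / 24`, converted at
#' `gain_kj_per_g` (7.79 kJ/g). When `available_g` is given (feeding mode)
#' the ingested mass is additionally capped by what the cell holds, so
#' depletion bookkeeping conserves mass.
#'
#' @param X intake rate, g/day per kg (from [intake()]).
#' @param body_mass animal mass, kg.
#' @param step_hours step duration, h.
#' @param gain_kj_per_g energy content of forage, kJ/g.
#' @param available_g grams of forage available in the cell, or `NULL` for
#'   the hypothetical (non-depleting) gain used in covariates.
#' @return A list with `G` (kJ) and `ingested_g` (g).
#' @export
#' @examples
#' gain(intake(40), body_mass = 100)$G
gain <- function(X, body_mass = 100, step_hours = 4, gain_kj_per_g = 7.79,
                 available_g = NULL) {
  stopifnot(all(X >= 0))
  ingested <- X * body_mass * step_hours / 24
  if (!is.null(available_g)) ingested <- pmin(ingested, pmax(available_g, 0))
  list(G = gain_kj_per_g * ingested, ingested_g = ingested)
}

#' Energy expenditure of a step
#'
#' Sum of the basal metabolic rate for one time step, a linear cost of
#' horizontal distance, and a linear cost of ascent (descent costs no climb
#' energy): `L = bmr_per_step + c_dist * SL + c_climb * max(0, dalt)`.
#' Always strictly positive via the BMR floor.
#'
#' @param sl step length, m (vectorized).
#' @param dalt altitude difference end minus start, m.
#' @param bmr_per_step basal metabolic cost per step, kJ (> 0).
#' @param c_dist distance cost, kJ/m.
#' @param c_climb ascent cost, kJ/m.
#' @return L in kJ.
#' @export
loss <- function(sl, dalt = 0, bmr_per_step = 1500, c_dist = 0.2,
                 c_climb = 2.7) {
  if (bmr_per_step <= 0) stop("bmr_per_step must be > 0", call. = FALSE)
  stopifnot(all(sl >= 0))
  bmr_per_step + c_dist * sl + c_climb * pmax(0, dalt)
}

#' Disturbance influence kernel
#'
#' Linear influence of an anthropogenic feature on step direction, scaled to
#' 1 at the feature and reaching 0 at the kind-specific zero-crossing
#' distance D0 (road 1500 m, recent cut 1600 m, regenerating cut 1300 m):
#' `f(D) = max(0, 1 - D/D0)`. Multiplied by `cos(theta)` it forms the SSF
#' disturbance covariates, so direction only matters close to a feature.
#'
#' @param D distance to the nearest feature, m (vectorized; `Inf` allowed).
#' @param kind `"road"`, `"recent_cut"` or `"regenerating_cut"`.
#' @param config a [movement_config()] carrying the D0 values.
#' @return values in [0, 1].
#' @export
#' @examples
#' f_disturbance(750, "road") # halfway to the 1500 m zero-crossing
f_disturbance <- function(D, kind, config = movement_config()) {
  kind <- match.arg(kind, c("road", "recent_cut", "regenerating_cut"))
  stopifnot(all(D >= 0))
  d0 <- config$disturbance[[kind]]
  pmax(0, 1 - D / d0)
}

#' Agent state
#'
#' The mutable state of one simulated (or replayed) individual: position,
#' heading, the FIFO ledger of the last 18 per-step net energies (kJ), the
#' bounded list of remembered patch clusters, the in-patch flag, and the
#' last location seen outside every cluster (used by the consecutive-location
#' cluster-founding rule).
#'
#' @param x,y position, m.
#' @param heading radians.
#' @param id individual label.
#' @param config a [movement_config()].
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(x, y, heading = 0, id = "ind1",
                        config = movement_config()) {
  structure(
    list(
      id = id, x = x, y = y, heading = heading,
      ledger = numeric(0),
      clusters = tibble::tibble(
        cx = numeric(0), cy = numeric(0),
        n = integer(0), order = integer(0)
      ),
      next_order = 1L,
      in_patch = FALSE,
      pending = NULL,
      config = config
    ),
    class = "agent_state"
  )
}

#' Push one step's net energy onto the 72-hour ledger
#'
#' Appends `G - L` to the FIFO ledger, evicts entries beyond the configured
#' length (18 steps = 3 days), and returns the updated state with the
#' current ledger sum. During warm-up (fewer than 18 completed steps) the
#' sum runs over the available entries.
#'
#' @param state an [agent_state()].
#' @param G,L per-step gain and loss, kJ.
#' @return The updated state; the ledger sum is `delta_e(state)`.
#' @export
update_ledger <- function(state, G, L) {
  led <- c(state$ledger, G - L)
  keep <- state$config$energetics$ledger_len
  if (length(led) > keep) led <- led[(length(led) - keep + 1):length(led)]
  state$ledger <- led
  state
}

#' @rdname update_ledger
#' @export
delta_e <- function(state) sum(state$ledger)

#' Update the spatial memory with a new location
#'
#' If the location lies within the patch radius (1600 m) of an existing
#' cluster centroid, the individual is in a patch: that cluster's centroid
#' moves to the running mean of its member locations, its count increments,
#' and it is refreshed as the most recently used. Otherwise, if the previous
#' location was also outside every cluster and within the patch radius of
#' the new one (`m_consec = 2` consecutive near locations), a new cluster is
#' founded at their midpoint, evicting the oldest cluster when the memory is
#' at capacity. Otherwise the individual is simply not in a patch.
#'
#' @param state an [agent_state()].
#' @param location numeric length-2 (x, y).
#' @return The updated state (`in_patch`, `clusters`).
#' @export
update_memory <- function(state, location) {
  cfg <- state$config$memory
  cl <- state$clusters
  if (nrow(cl) > 0) {
    d <- sqrt((cl$cx - location[1])^2 + (cl$cy - location[2])^2)
    i <- which.min(d)
    if (d[i] < cfg$patch_radius) {
      n <- cl$n[i]
      cl$cx[i] <- (n * cl$cx[i] + location[1]) / (n + 1)
      cl$cy[i] <- (n * cl$cy[i] + location[2]) / (n + 1)
      cl$n[i] <- n + 1L
      cl$order[i] <- state$next_order
      state$next_order <- state$next_order + 1L
      state$clusters <- cl
      state$in_patch <- TRUE
      state$pending <- NULL
      return(state)
    }
  }
  state$in_patch <- FALSE
  if (!is.null(state$pending)) {
    dp <- sqrt(sum((state$pending - location)^2))
    if (dp < cfg$patch_radius) {
      # two consecutive out-of-cluster locations close together -> new cluster
      newc <- tibble::tibble(
        cx = (state$pending[1] + location[1]) / 2,
        cy = (state$pending[2] + location[2]) / 2,
        n = 2L, order = state$next_order
      )
      state$next_order <- state$next_order + 1L
      cl <- dplyr::bind_rows(cl, newc)
      if (nrow(cl) > cfg$k_mem) {
        cl <- cl[order(cl$order, decreasing = TRUE)[seq_len(cfg$k_mem)], ]
      }
      state$clusters <- cl
      state$in_patch <- TRUE
      state$pending <- NULL
      return(state)
    }
  }
  state$pending <- as.numeric(location)
  state
}

#' Memory direction covariate
#'
#' The cosine of the minimum unsigned angle between a step's bearing and the
#' directions from its start to each remembered cluster centroid; 0 when the
#' memory is empty (no directional pull).
#'
#' @param start numeric length-2 (x, y).
#' @param bearing step direction, radians (vectorized).
#' @param clusters the `clusters` tibble of an [agent_state()].
#' @return values in [-1, 1], one per bearing.
#' @export
cos_theta_mem <- function(start, bearing, clusters) {
  if (is.null(clusters) || nrow(clusters) == 0) {
    return(rep(0, length(bearing)))
  }
  dirs <- atan2(clusters$cy - start[2], clusters$cx - start[1])
  ang <- abs(wrap_pi(outer(bearing, dirs, "-")))
  cos(apply(ang, 1, min))
}
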