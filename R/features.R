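#' Anthropogenic feature layers
#'
#' Holds the disturbance features of one landscape year as masks aligned with
#' a [landscape_grid()]: roads, recent cuts (with age in years since cut),
#' regenerating cuts (5--20 years) and burned areas. Recent cuts carry an age
#' matrix (`NA` = not a recent cut); [advance_year()] increments ages and
#' reclassifies cuts that reach age 5 as regenerating, so a cell stays a
#' recent cut for at most 5 consecutive years.
#'
#' @param grid the [landscape_grid()] the masks align with.
#' @param road,regenerating_cut,burned logical matrices (default all-FALSE).
#' @param recent_cut_age integer matrix of ages, `NA` where not cut.
#' @param year label for this snapshot (integer).
#' @return An object of class `feature_layers`.
#' @export
feature_layers <- function(grid, road = NULL, recent_cut_age = NULL,
                           regenerating_cut = NULL, burned = NULL,
                           year = 0L) {
  blank <- matrix(FALSE, grid$nrows, grid$ncols)
  road <- road %||% blank
  regenerating_cut <- regenerating_cut %||% blank
  burned <- burned %||% blank
  recent_cut_age <- recent_cut_age %||%
    matrix(NA_integer_, grid$nrows, grid$ncols)
  dims <- list(road, recent_cut_age, regenerating_cut, burned)
  if (!all(vapply(dims, function(m) all(dim(m) == c(grid$nrows, grid$ncols)),
    logical(1)
  ))) {
    stop("feature masks must align with the grid", call. = FALSE)
  }
  f <- structure(
    list(
      road = road, recent_cut_age = recent_cut_age,
      regenerating_cut = regenerating_cut, burned = burned,
      year = as.integer(year),
      origin = grid$origin, cell_size = grid$cell_size,
      nrows = grid$nrows, ncols = grid$ncols
    ),
    class = "feature_layers"
  )
  f$centers <- lapply(
    stats::setNames(nm = c("road", "recent_cut", "regenerating_cut")),
    function(k) feature_cell_centers(f, k)
  )
  f
}

feature_mask <- function(features, kind) {
  switch(kind,
    road = features$road,
    recent_cut = !is.na(features$recent_cut_age),
    regenerating_cut = features$regenerating_cut,
    burned = features$burned,
    stop("unknown feature kind: ", kind, call. = FALSE)
  )
}

# matrix of (x, y) centre coordinates of feature cells of a kind
feature_cell_centers <- function(features, kind) {
  m <- feature_mask(features, kind)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  }
  s <- features$cell_size
  cbind(
    x = features$origin[1] + (idx[, 2] - 0.5) * s,
    y = features$origin[2] + (features$nrows - idx[, 1] + 0.5) * s
  )
}

#' Distance and relative angle to the nearest feature
#'
#' Finds the nearest feature cell of the given kind and returns the Euclidean
#' distance `D` (m) and `cos(theta)` where theta is the angle between the
#' step direction (`heading`) and the direction from the point to that cell's
#' centre. A point lying inside a feature cell has `D = 0` and
#' `cos_theta = 1` (direction undefined at zero distance). If no feature cell
#' of that kind exists, `D = Inf` and `cos_theta = 0`, so the linear
#' disturbance kernel contributes nothing.
#'
#' @param point numeric length-2 (x, y) in metres.
#' @param heading step direction, radians.
#' @param features a [feature_layers()].
#' @param kind one of `"road"`, `"recent_cut"`, `"regenerating_cut"`.
#' @return A list with elements `distance` and `cos_theta`.
#' @export
distance_angle_to_feature <- function(point, heading, features, kind) {
  kind <- match.arg(kind, c("road", "recent_cut", "regenerating_cut"))
  ctr <- features$centers[[kind]]
  if (nrow(ctr) == 0) {
    return(list(distance = Inf, cos_theta = 0))
  }
  # inside a feature cell footprint -> distance zero by convention
  s <- features$cell_size
  col <- floor((point[1] - features$origin[1]) / s) + 1
  row <- features$nrows - floor((point[2] - features$origin[2]) / s)
  if (row >= 1 && row <= features$nrows && col >= 1 && col <= features$ncols &&
    feature_mask(features, kind)[row, col]) {
    return(list(distance = 0, cos_theta = 1))
  }
  dx <- ctr[, 1] - point[1]
  dy <- ctr[, 2] - point[2]
  d2 <- dx * dx + dy * dy
  i <- which.min(d2)
  ang <- atan2(dy[i], dx[i])
  list(distance = sqrt(d2[i]), cos_theta = cos(wrap_pi(ang - heading)))
}

#' Advance the feature layers by one year
#'
#' Increments recent-cut ages; cuts reaching age 5 are reclassified as
#' regenerating cuts, and the cells of `new_cuts` become recent cuts of age
#' 0. The total cut footprint (recent + regenerating) never shrinks.
#'
#' @param features a [feature_layers()].
#' @param new_cuts logical matrix of newly cut cells (default none).
#' @return A new `feature_layers` with `year` incremented.
#' @export
advance_year <- function(features, new_cuts = NULL) {
  age <- features$recent_cut_age + 1L
  aged_out <- !is.na(age) & age >= 5L
  regen <- features$regenerating_cut | aged_out
  age[aged_out] <- NA_integer_
  if (!is.null(new_cuts)) {
    if (!all(dim(new_cuts) == dim(age))) {
      stop("new_cuts must align with the grid", call. = FALSE)
    }
    age[new_cuts] <- 0L
    regen[new_cuts] <- FALSE
  }
  out <- features
  out$recent_cut_age <- age
  out$regenerating_cut <- regen
  out$year <- features$year + 1L
  out$centers <- lapply(
    stats::setNames(nm = c("road", "recent_cut", "regenerating_cut")),
    function(k) feature_cell_centers(out, k)
  )
  out
}
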