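#' Read / write GPS tracks
#'
#' Tracks are tibbles with columns `id` (individual), `t` (POSIXct,
#' ISO-8601 in the file), `x`, `y` (projected metres). The nominal fix
#' interval is 4 h.
#'
#' @param path CSV file path.
#' @param tracks a track tibble.
#' @return `read_tracks()` returns a track tibble ordered by id and time;
#'   `write_tracks()` returns `path` invisibly.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "t", "x", "y")
  if (!all(need %in% names(df))) {
    stop("track CSV must have columns id, t, x, y", call. = FALSE)
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(
      id = as.character(.data$id),
      t = as.POSIXct(.data$t, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    ) |>
    dplyr::arrange(.data$id, .data$t)
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks
  out$t <- format(out$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Decompose tracks into movement steps
#'
#' Breaks each individual's path into straight-line steps between successive
#' fixes at the nominal interval. Fix pairs whose spacing deviates from the
#' nominal interval by more than the tolerance are treated as gaps: no step
#' spans the gap and the turning-angle chain restarts after it (the first
#' step of each contiguous segment has `ta = NA`). Steps can be restricted
#' to the winter window (a step is kept when its start fix falls inside the
#' window).
#'
#' @param tracks a track tibble (`id`, `t`, `x`, `y`).
#' @param window if `TRUE`, keep only steps starting inside the winter
#'   window of `config`.
#' @param tol fractional tolerance on the fix interval (default 0.1).
#' @param config a [movement_config()].
#' @return A step tibble with columns `id`, `t0`, `t1`, `x0`, `y0`, `x1`,
#'   `y1`, `sl` (m), `bearing` (radians), `ta` (radians in (-pi, pi], `NA`
#'   when no previous step exists).
#' @export
decompose_steps <- function(tracks, window = FALSE, tol = 0.1,
                            config = movement_config()) {
  stopifnot(all(c("id", "t", "x", "y") %in% names(tracks)))
  dt_nom <- config$winter$fix_interval_hours * 3600

  one <- function(df, id) {
    df <- df[order(df$t), ]
    df$id <- id
    if (any(duplicated(df$t))) {
      stop("timestamps must be strictly increasing within an individual",
        call. = FALSE
      )
    }
    n <- nrow(df)
    if (n < 2) {
      stop("need at least 2 fixes per individual", call. = FALSE)
    }
    dt <- as.numeric(difftime(df$t[-1], df$t[-n], units = "secs"))
    ok <- abs(dt - dt_nom) <= tol * dt_nom
    st <- tibble::tibble(
      id = df$id[1],
      t0 = df$t[-n][ok], t1 = df$t[-1][ok],
      x0 = df$x[-n][ok], y0 = df$y[-n][ok],
      x1 = df$x[-1][ok], y1 = df$y[-1][ok]
    )
    st$sl <- sqrt((st$x1 - st$x0)^2 + (st$y1 - st$y0)^2)
    st$bearing <- bearing_of(st$x1 - st$x0, st$y1 - st$y0)
    # ta defined only when the previous fix pair was also a usable step
    prev_ok <- c(FALSE, ok[-length(ok)])[ok]
    prev_bearing <- c(NA_real_, st$bearing[-nrow(st)])
    st$ta <- ifelse(prev_ok, wrap_pi(st$bearing - prev_bearing), NA_real_)
    st
  }

  steps <- tracks |>
    dplyr::group_split(.data$id) |>
    purrr::map(~ one(.x, .x$id[1])) |>
    dplyr::bind_rows() |>
    dplyr::select(
      "id", "t0", "t1", "x0", "y0", "x1", "y1", "sl", "bearing", "ta"
    )
  if (isTRUE(window)) {
    steps <- steps[in_winter(steps$t0, config), ]
  }
  if (nrow(steps) == 0) stop("no usable steps", call. = FALSE)
  steps
}

#' Pooled empirical step-length and turning-angle distributions
#'
#' Pools steps of all individuals (normally restricted to the winter window)
#' into raw empirical samples; random candidate steps are drawn from these
#' by resampling with replacement, independently for length and angle.
#'
#' @param steps a step tibble from [decompose_steps()].
#' @return An object of class `empirical_distros` with elements `sl` and
#'   `ta` (numeric samples).
#' @export
empirical_distributions <- function(steps) {
  sl <- steps$sl
  ta <- steps$ta[!is.na(steps$ta)]
  if (length(sl) == 0 || length(ta) == 0) {
    stop("empty step pool", call. = FALSE)
  }
  structure(list(sl = sl, ta = ta), class = "empirical_distros")
}

#' @export
print.empirical_distros <- function(x, ...) {
  cat(
    "<empirical_distros>", length(x$sl), "step lengths (median",
    round(stats::median(x$sl)), "m),", length(x$ta), "turning angles\n"
  )
  invisible(x)
}

#' Draw random candidate steps
#'
#' Each candidate shares the start point; its length and turning angle are
#' independent resamples (with replacement) of the pooled empirical
#' distributions, its bearing is `heading + ta`, and its end point follows.
#'
#' @param start numeric length-2 (x, y).
#' @param heading current heading, radians.
#' @param distros an [empirical_distributions()] object.
#' @param n number of candidates.
#' @return A tibble with columns `sl`, `ta`, `bearing`, `x0`, `y0`, `x1`,
#'   `y1`.
#' @export
draw_random_steps <- function(start, heading, distros, n) {
  stopifnot(n >= 1)
  sl <- distros$sl[sample.int(length(distros$sl), n, replace = TRUE)]
  ta <- distros$ta[sample.int(length(distros$ta), n, replace = TRUE)]
  bearing <- wrap_pi(heading + ta)
  tibble::new_tibble(list(
    sl = sl, ta = ta, bearing = bearing,
    x0 = rep(start[1], n), y0 = rep(start[2], n),
    x1 = start[1] + sl * cos(bearing),
    y1 = start[2] + sl * sin(bearing)
  ), nrow = n)
}
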