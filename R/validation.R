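# Emergent-pattern validation: home ranges (95% MCP), resource selection
# functions on landcover classes, beta-vector correlations between real and
# simulated individuals, and scenario contrasts.

#' 95% minimum convex polygon home range
#'
#' Drops the `floor((1 - level) * n)` points farthest from the centroid
#' (Euclidean distance), takes the convex hull of the rest, and computes the
#' shoelace area. Degenerate inputs (all points collinear or coincident)
#' return zero area with a flag.
#'
#' @param points a two-column matrix or a tibble with `x` and `y`.
#' @param level retained fraction (default 0.95).
#' @return An object of class `home_range`: `polygon` (vertex tibble,
#'   counter-clockwise), `area_km2`, `n_used`, `degenerate`.
#' @export
#' @examples
#' hr <- mcp95(cbind(runif(50, 0, 1000), runif(50, 0, 1000)))
#' hr$area_km2
mcp95 <- function(points, level = 0.95) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  d <- sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2)
  drop_n <- floor((1 - level) * n)
  keep <- if (drop_n > 0) order(d)[seq_len(n - drop_n)] else seq_len(n)
  pts <- points[keep, , drop = FALSE]
  h <- grDevices::chull(pts) # clockwise vertex indices
  poly <- pts[rev(h), , drop = FALSE] # counter-clockwise
  # shoelace
  xs <- poly[, 1]
  ys <- poly[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  structure(
    list(
      polygon = tibble::tibble(x = poly[, 1], y = poly[, 2]),
      area_km2 = area / 1e6, n_used = nrow(pts),
      degenerate = nrow(poly) < 3 || area == 0
    ),
    class = "home_range"
  )
}

#' @export
print.home_range <- function(x, ...) {
  cat(
    "<home_range> 95% MCP over", x$n_used, "points:",
    format(x$area_km2, digits = 4), "km2",
    if (x$degenerate) "(degenerate)" else "", "\n"
  )
  invisible(x)
}

#' Resource selection function on landcover classes
#'
#' Contrasts used locations against `n_random` available points drawn
#' uniformly inside the availability polygon, with a logistic regression of
#' used (1) / available (0) on presence/absence dummies of the landcover
#' class at each point. The reference class (open conifer stand without
#' lichen, class 9, by default) carries no coefficient. Classes present in
#' the data but entirely used or entirely available show complete
#' separation; their coefficients are flagged non-finite and excluded from
#' downstream correlations.
#'
#' @param used a tibble/matrix of used locations (`x`, `y`).
#' @param polygon availability polygon (two-column vertex matrix), e.g. the
#'   95% MCP; `NULL` means the whole grid extent.
#' @param grid a [landscape_grid()].
#' @param n_random number of available points (default 10 per used point).
#' @param reference_class class code of the reference level.
#' @param seed RNG seed or `NULL`.
#' @return An object of class `rsf_fit`: tibble `coefs` (`class`, `beta`,
#'   `se`, `conf_low`, `conf_high`, `separated`), the reference class, and
#'   counts.
#' @export
rsf_fit <- function(used, polygon = NULL, grid, n_random = 10 * nrow(used),
                    reference_class = 9L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(used)) used <- cbind(used$x, used$y)
  used <- used[stats::complete.cases(used), , drop = FALSE]
  if (nrow(used) < 1) stop("no used points", call. = FALSE)

  avail <- sample_available(polygon, grid, n_random)
  cls_u <- grid_value(grid, "cover_type", used[, 1], used[, 2])
  cls_a <- grid_value(grid, "cover_type", avail[, 1], avail[, 2])
  y <- c(rep(1L, length(cls_u)), rep(0L, length(cls_a)))
  cls <- c(cls_u, cls_a)

  present <- sort(unique(cls))
  if (!reference_class %in% present) {
    # fall back to the most available class as reference
    reference_class <- as.integer(names(sort(table(cls_a),
      decreasing = TRUE
    ))[1])
  }
  f <- factor(cls, levels = c(reference_class, setdiff(present, reference_class)))
  fit <- if (nlevels(f) < 2) {
    suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
  } else {
    suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
  }
  sm <- summary(fit)$coefficients
  nm <- paste0("f", setdiff(present, reference_class))
  beta <- sm[match(nm, rownames(sm)), 1]
  se <- sm[match(nm, rownames(sm)), 2]
  separated <- !is.na(beta) & (abs(beta) > 10 & se > 50)
  beta[separated] <- NA_real_
  coefs <- tibble::tibble(
    class = setdiff(present, reference_class),
    beta = unname(beta), se = unname(se),
    conf_low = unname(beta - 1.96 * se),
    conf_high = unname(beta + 1.96 * se),
    separated = unname(separated)
  )
  structure(
    list(
      coefs = coefs, reference_class = reference_class,
      n_used = length(cls_u), n_available = length(cls_a),
      glm = fit
    ),
    class = "rsf_fit"
  )
}

# uniform points inside a polygon (rejection from the bounding box) or over
# the grid extent when polygon is NULL
sample_available <- function(polygon, grid, n) {
  if (is.null(polygon)) {
    x <- stats::runif(n, grid$origin[1], grid$origin[1] +
      grid$ncols * grid$cell_size)
    y <- stats::runif(n, grid$origin[2], grid$origin[2] +
      grid$nrows * grid$cell_size)
    return(cbind(x, y))
  }
  polygon <- as.matrix(polygon)
  out <- matrix(numeric(0), 0, 2)
  bx <- range(polygon[, 1])
  by <- range(polygon[, 2])
  while (nrow(out) < n) {
    k <- max(100, 2 * (n - nrow(out)))
    x <- stats::runif(k, bx[1], bx[2])
    y <- stats::runif(k, by[1], by[2])
    ok <- point_in_polygon(x, y, polygon) & in_grid(grid, x, y)
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(
    "<rsf_fit>", x$n_used, "used vs", x$n_available,
    "available points; reference class", x$reference_class, "\n"
  )
  print(x$coefs, n = 5)
  invisible(x)
}

#' Correlate real and simulated selection coefficient vectors
#'
#' For each simulated run, computes Pearson R and Spearman r_s between the
#' real individual's RSF beta vector and the run's, over the classes with
#' finite coefficients in both. `mode = "significant"` keeps only classes
#' whose 95% CI excludes zero in the real model. Fewer than 3 shared
#' coefficients yields `NA` with a flag.
#'
#' @param real_rsf an [rsf_fit()] for the real individual.
#' @param sim_rsfs a list of [rsf_fit()]s for the simulated runs.
#' @param mode `"all"` or `"significant"`.
#' @return A tibble (`run`, `pearson`, `spearman`, `n_shared`, `defined`).
#' @export
compare_beta_vectors <- function(real_rsf, sim_rsfs, mode = c("all", "significant")) {
  mode <- match.arg(mode)
  rc <- real_rsf$coefs
  if (mode == "significant") {
    rc <- rc[!is.na(rc$beta) & (rc$conf_low > 0 | rc$conf_high < 0), ]
  }
  purrr::map_dfr(seq_along(sim_rsfs), function(i) {
    sc <- sim_rsfs[[i]]$coefs
    shared <- merge(
      rc[!is.na(rc$beta), c("class", "beta")],
      sc[!is.na(sc$beta), c("class", "beta")],
      by = "class", suffixes = c("_real", "_sim")
    )
    if (nrow(shared) < 3) {
      return(tibble::tibble(
        run = i, pearson = NA_real_, spearman = NA_real_,
        n_shared = nrow(shared), defined = FALSE
      ))
    }
    tibble::tibble(
      run = i,
      pearson = stats::cor(shared$beta_real, shared$beta_sim),
      spearman = stats::cor(shared$beta_real, shared$beta_sim,
        method = "spearman"
      ),
      n_shared = nrow(shared), defined = TRUE
    )
  })
}

#' Home-range size index
#'
#' A symmetric ratio index comparing simulated to real home-range areas:
#' `area_sim / area_real - 1` when the simulated range is the larger,
#' `-(area_real / area_sim - 1)` otherwise. Zero means equal areas; the
#' index is antisymmetric under swapping the two.
#'
#' @param area_sim,area_real positive areas (vectorized).
#' @return the index c.
#' @export
#' @examples
#' homerange_index(2, 1) # +1
homerange_index <- function(area_sim, area_real) {
  if (any(area_sim <= 0) || any(area_real <= 0)) {
    stop("areas must be positive", call. = FALSE)
  }
  ifelse(area_sim >= area_real,
    area_sim / area_real - 1,
    -(area_real / area_sim - 1)
  )
}

#' Contrast two landscape scenarios
#'
#' Given per-run location sets from two scenario simulations (e.g. current
#' landscape vs hardwood encroachment), fits one pooled RSF per run with
#' availability over the whole extent, and compares the per-class beta
#' distributions across scenarios with a two-sample Wilcoxon-Mann-Whitney
#' rank test; per-individual 95% MCP areas are compared the same way.
#' Classes absent from one scenario's fits are excluded with a flag.
#'
#' @param runs_a,runs_b lists of track tibbles (`id`, `x`, `y`), one per
#'   simulation run.
#' @param grid_a,grid_b the [landscape_grid()]s of the two scenarios.
#' @param n_random available points per run RSF.
#' @param reference_class reference landcover class code.
#' @param seed RNG seed or `NULL`.
#' @return A list of class `scenario_contrast`: `beta` (per-run per-class
#'   tibble), `beta_tests` (`class`, `w`, `p_value`, `excluded`),
#'   `area` (per-run per-individual MCP areas) and `area_test`.
#' @export
scenario_contrast <- function(runs_a, runs_b, grid_a, grid_b,
                              n_random = 5000, reference_class = 9L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(runs_a) < 2 || length(runs_b) < 2) {
    stop("need >= 2 runs per scenario", call. = FALSE)
  }
  run_betas <- function(runs, grid, scen) {
    purrr::map_dfr(seq_along(runs), function(r) {
      rsf <- rsf_fit(runs[[r]],
        polygon = NULL, grid = grid,
        n_random = n_random, reference_class = reference_class
      )
      dplyr::mutate(rsf$coefs, scenario = scen, run = r)
    })
  }
  beta <- dplyr::bind_rows(
    run_betas(runs_a, grid_a, "a"),
    run_betas(runs_b, grid_b, "b")
  )
  classes <- sort(unique(beta$class))
  beta_tests <- purrr::map_dfr(classes, function(cl) {
    a <- beta$beta[beta$scenario == "a" & beta$class == cl]
    b <- beta$beta[beta$scenario == "b" & beta$class == cl]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(
        class = cl, w = NA_real_, p_value = NA_real_,
        excluded = TRUE
      ))
    }
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    tibble::tibble(
      class = cl, w = unname(wt$statistic),
      p_value = wt$p.value, excluded = FALSE
    )
  })
  run_areas <- function(runs, scen) {
    purrr::map_dfr(seq_along(runs), function(r) {
      df <- runs[[r]]
      df |>
        dplyr::group_by(.data$id) |>
        dplyr::summarise(
          area_km2 = mcp95(cbind(.data$x, .data$y))$area_km2,
          .groups = "drop"
        ) |>
        dplyr::mutate(scenario = scen, run = r)
    })
  }
  area <- dplyr::bind_rows(run_areas(runs_a, "a"), run_areas(runs_b, "b"))
  at <- stats::wilcox.test(
    area$area_km2[area$scenario == "a"],
    area$area_km2[area$scenario == "b"],
    exact = FALSE
  )
  structure(
    list(
      beta = tibble::as_tibble(beta), beta_tests = beta_tests,
      area = area,
      area_test = tibble::tibble(w = unname(at$statistic), p_value = at$p.value)
    ),
    class = "scenario_contrast"
  )
}
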