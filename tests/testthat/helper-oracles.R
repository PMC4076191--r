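# Independent oracle implementations, deliberately written as naive loops so
# they share no code path with the package.

# 3x3 gradient-magnitude stencil: per-axis central difference (one-sided at
# the borders) smoothed with (1,2,1)/4 across the other axis, evaluated cell
# by cell.
oracle_edge <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  at <- function(r, c) m[min(max(r, 1), nr), min(max(c, 1), nc)]
  dx <- function(r, c) {
    if (nc == 1) {
      0
    } else if (c == 1) {
      at(r, 2) - at(r, 1)
    } else if (c == nc) {
      at(r, nc) - at(r, nc - 1)
    } else {
      (at(r, c + 1) - at(r, c - 1)) / 2
    }
  }
  dy <- function(r, c) {
    if (nr == 1) {
      0
    } else if (r == 1) {
      at(2, c) - at(1, c)
    } else if (r == nr) {
      at(nr, c) - at(nr - 1, c)
    } else {
      (at(r + 1, c) - at(r - 1, c)) / 2
    }
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rm1 <- max(r - 1, 1)
      rp1 <- min(r + 1, nr)
      cm1 <- max(c - 1, 1)
      cp1 <- min(c + 1, nc)
      gx <- (dx(rm1, c) + 2 * dx(r, c) + dx(rp1, c)) / 4
      gy <- (dy(r, cm1) + 2 * dy(r, c) + dy(r, cp1)) / 4
      out[r, c] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# gift-wrapping convex hull + shoelace area (independent of grDevices::chull)
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) {
    return(0)
  }
  start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    nxt <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_n <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && d_j > d_n)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
    if (length(hull) > n) break
  }
  xs <- pts[hull, 1]
  ys <- pts[hull, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# midranks computed by counting, then the Pearson formula on the ranks
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive nearest feature cell: scan every cell of the mask
oracle_nearest_feature <- function(point, mask, origin, cell_size) {
  nr <- nrow(mask)
  best <- Inf
  best_xy <- NULL
  for (r in seq_len(nr)) {
    for (c in seq_len(ncol(mask))) {
      if (!mask[r, c]) next
      cx <- origin[1] + (c - 0.5) * cell_size
      cy <- origin[2] + (nr - r + 0.5) * cell_size
      d <- sqrt((cx - point[1])^2 + (cy - point[2])^2)
      if (d < best) {
        best <- d
        best_xy <- c(cx, cy)
      }
    }
  }
  list(distance = best, xy = best_xy)
}

# dense grid maximizer of the 1-covariate conditional log-likelihood
oracle_clogit_1d <- function(x, case, stratum, lo = -5, hi = 5) {
  ll <- function(b) {
    eta <- b * x
    sum(tapply(seq_along(eta), stratum, function(ii) {
      eta[ii][case[ii] == 1] - log(sum(exp(eta[ii])))
    }))
  }
  grid1 <- seq(lo, hi, length.out = 2001)
  b1 <- grid1[which.max(vapply(grid1, ll, numeric(1)))]
  grid2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-5)
  grid2[which.max(vapply(grid2, ll, numeric(1)))]
}
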