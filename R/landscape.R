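#' Gridded landscape
#'
#' A `landscape_grid` holds co-registered 25 m raster layers on a projected
#' planar grid: integer landcover class (`cover_type`, codes 1--15), lichen
#' biomass (`lichen`, g/m2), percentage canopy cover (`cover`), canopy-cover
#' gradient magnitude (`edge`, %/cell) and `altitude` (m). Lichen and cover
#' are initialised from the per-class attribute table and lichen may then be
#' depleted (never below zero) by foraging agents; the class-derived baseline
#' is kept alongside so scenario transforms can re-derive layers cheaply.
#'
#' Matrices are stored with row 1 at the top (north), matching ESRI ASCII
#' order. Cell footprints are half-open: column `c` covers
#' `[x0 + (c-1)s, x0 + c s)` and a point maps to the cell containing it.
#'
#' @param cover_type integer matrix of class codes.
#' @param altitude numeric matrix (m), same shape; a constant is recycled.
#' @param origin numeric length-2, (x, y) of the lower-left corner in metres.
#' @param cell_size cell edge length in metres.
#' @param config a [movement_config()]; supplies the class attribute table.
#' @return An object of class `landscape_grid`.
#' @export
#' @examples
#' g <- landscape_grid(matrix(11L, 4, 4), altitude = 300)
#' g$lichen[1, 1]
landscape_grid <- function(cover_type, altitude = 0, origin = c(0, 0),
                           cell_size = config$cell_size,
                           config = movement_config()) {
  cover_type <- as.matrix(cover_type)
  storage.mode(cover_type) <- "integer"
  lut <- config$landcover
  bad <- setdiff(unique(as.vector(cover_type)), lut$class)
  if (length(bad)) {
    stop("unknown landcover class code(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(altitude) == 1) {
    altitude <- matrix(altitude, nrow(cover_type), ncol(cover_type))
  }
  altitude <- as.matrix(altitude)
  stopifnot(all(dim(altitude) == dim(cover_type)))
  idx <- match(as.vector(cover_type), lut$class)
  lichen <- matrix(lut$lichen[idx], nrow(cover_type), ncol(cover_type))
  cover <- matrix(lut$cover[idx], nrow(cover_type), ncol(cover_type))
  g <- structure(
    list(
      origin = as.numeric(origin), cell_size = cell_size,
      nrows = nrow(cover_type), ncols = ncol(cover_type),
      cover_type = cover_type, lichen = lichen, cover = cover,
      edge = derive_edge(cover), altitude = altitude,
      landcover = lut
    ),
    class = "landscape_grid"
  )
  g
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(
    "<landscape_grid> ", x$nrows, "x", x$ncols, " cells of ", x$cell_size,
    " m, origin (", x$origin[1], ", ", x$origin[2], ")\n",
    sep = ""
  )
  tab <- sort(table(x$cover_type), decreasing = TRUE)
  cat(
    "  classes:",
    paste0(names(tab), " (", round(100 * tab / sum(tab)), "%)",
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

# --- point/cell geometry ----------------------------------------------------

#' Map points to cells and back
#'
#' `point_to_cell()` returns the (row, col) of the cell containing each
#' point; `cell_center()` the centre coordinates of given cells;
#' `in_grid()` whether points fall inside the grid extent (half-open on the
#' top/right edges).
#'
#' @param grid a [landscape_grid()].
#' @param x,y point coordinates (m), vectorized.
#' @param row,col cell indices (1-based; row 1 is the top/north row).
#' @return `point_to_cell()`: a two-column integer matrix (row, col);
#'   `cell_center()`: a two-column numeric matrix (x, y); `in_grid()`:
#'   a logical vector.
#' @export
point_to_cell <- function(grid, x, y) {
  s <- grid$cell_size
  col <- floor((x - grid$origin[1]) / s) + 1L
  row <- grid$nrows - floor((y - grid$origin[2]) / s)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname point_to_cell
#' @export
cell_center <- function(grid, row, col) {
  s <- grid$cell_size
  cbind(
    x = grid$origin[1] + (col - 0.5) * s,
    y = grid$origin[2] + (grid$nrows - row + 0.5) * s
  )
}

#' @rdname point_to_cell
#' @export
in_grid <- function(grid, x, y) {
  s <- grid$cell_size
  x >= grid$origin[1] & x < grid$origin[1] + grid$ncols * s &
    y >= grid$origin[2] & y < grid$origin[2] + grid$nrows * s
}

# value of a layer at points (vectorized); points must be inside the grid
grid_value <- function(grid, layer, x, y) {
  rc <- point_to_cell(grid, x, y)
  grid[[layer]][cbind(rc[, 1], rc[, 2])]
}

# --- edge operator ----------------------------------------------------------

#' Canopy-cover gradient magnitude over the 3x3 Moore neighbourhood
#'
#' Computes per-cell gradient magnitude `sqrt(gx^2 + gy^2)` of a percentage
#' field with a normalised Sobel operator: along each axis a central
#' difference `(v[i+1] - v[i-1])/2` (one-sided at the borders), smoothed
#' across the perpendicular axis with weights (1, 2, 1)/4. In the interior
#' this equals the Sobel stencil divided by 8, so a linear ramp of 10 %/cell
#' yields an edge value of exactly 10 %/cell. Units: %/cell.
#'
#' @param cover numeric matrix (percentage canopy cover).
#' @return numeric matrix of gradient magnitudes, same shape.
#' @export
#' @examples
#' derive_edge(matrix(50, 5, 5)) # constant field -> all zero
derive_edge <- function(cover) {
  cover <- as.matrix(cover)
  nr <- nrow(cover)
  nc <- ncol(cover)
  if (nr == 1 && nc == 1) {
    return(matrix(0, 1, 1))
  }

  diff_axis <- function(m, along_cols) {
    # central difference along columns of m (one-sided at borders)
    n <- ncol(m)
    if (n == 1) {
      return(matrix(0, nrow(m), 1))
    }
    d <- matrix(0, nrow(m), n)
    if (n > 2) d[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / 2
    d[, 1] <- m[, 2] - m[, 1]
    d[, n] <- m[, n] - m[, n - 1]
    d
  }
  smooth_axis <- function(m) {
    # (1,2,1)/4 smoothing along rows of m, replicate padding
    n <- nrow(m)
    if (n == 1) {
      return(m)
    }
    up <- m[c(1, 1:(n - 1)), , drop = FALSE]
    dn <- m[c(2:n, n), , drop = FALSE]
    (up + 2 * m + dn) / 4
  }
  # x increases with column index, y decreases with row index (row 1 = north)
  gx <- smooth_axis(diff_axis(cover))
  gy_row <- t(diff_axis(t(cover))) # difference down rows
  # smoothing across columns for the row-difference
  gy <- t(smooth_axis(t(gy_row)))
  sqrt(gx^2 + gy^2)
}

# --- ESRI ASCII grid IO -----------------------------------------------------

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text single-band raster IO (the `.asc` format: a 6-line header
#' followed by rows of values, northernmost row first). `read_ascii_grid()`
#' returns a list with the value `matrix`, `origin` (xll, yll), `cell_size`
#' and `nodata`; `write_ascii_grid()` writes a matrix in the same layout.
#'
#' @param path file path.
#' @param m numeric matrix (row 1 = north).
#' @param origin numeric length-2 lower-left corner.
#' @param cell_size cell size in metres.
#' @param nodata value written for `NA` cells.
#' @return See description; `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) {
    stop("cannot open raster: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
    quiet = TRUE
  )
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
      call. = FALSE
    )
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  list(
    matrix = m, origin = c(xll, yll), cell_size = hdr$cellsize,
    nodata = hdr$nodata_value
  )
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(m, path, origin = c(0, 0), cell_size = 25,
                             nodata = -9999) {
  m <- as.matrix(m)
  body <- m
  body[is.na(body)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(origin[1], scientific = FALSE)),
    paste("yllcorner", format(origin[2], scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  writeLines(apply(body, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Load a landscape from raster files
#'
#' Reads a classified landcover raster and a DEM (ESRI ASCII grids on the
#' same 25 m grid) and assembles a [landscape_grid()], initialising lichen
#' and canopy cover from the class attribute table and deriving the edge
#' layer.
#'
#' @param cover_path path to the landcover class raster.
#' @param dem_path path to the DEM raster; `NULL` for a flat landscape.
#' @param config a [movement_config()]; its `landcover` table must cover all
#'   class codes present.
#' @return A [landscape_grid()].
#' @export
load_landscape <- function(cover_path, dem_path = NULL,
                           config = movement_config()) {
  cov <- read_ascii_grid(cover_path)
  alt <- if (is.null(dem_path)) 0 else {
    dem <- read_ascii_grid(dem_path)
    if (!all(dim(dem$matrix) == dim(cov$matrix)) ||
      any(abs(dem$origin - cov$origin) > 1e-6) ||
      abs(dem$cell_size - cov$cell_size) > 1e-9) {
      stop("DEM and landcover rasters are not co-registered", call. = FALSE)
    }
    dem$matrix
  }
  landscape_grid(cov$matrix,
    altitude = alt, origin = cov$origin,
    cell_size = cov$cell_size, config = config
  )
}

# --- encroachment scenario --------------------------------------------------

#' Encroachment scenario specification
#'
#' Parameters of the hardwood-encroachment landscape transform: the extent is
#' tiled into square quadrats of `quadrat_area` (matching forest-harvesting
#' block size) and, inside a centred square covering `converted_fraction` of
#' each quadrat, every cell not in a protected class is converted to
#' `target_class` (mixed/deciduous forest by default). Fixed open areas and
#' water bodies are protected by default.
#'
#' @param quadrat_area quadrat area in km2 (default 225).
#' @param converted_fraction fraction of each quadrat converted, in (0, 1].
#' @param target_class class code written into converted cells.
#' @param protected_classes class codes never overwritten.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(quadrat_area = 225, converted_fraction = 0.70,
                          target_class = 12L, protected_classes = c(1L, 3L)) {
  if (!(converted_fraction > 0 && converted_fraction <= 1)) {
    stop("converted_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      quadrat_area = quadrat_area, converted_fraction = converted_fraction,
      target_class = as.integer(target_class),
      protected_classes = as.integer(protected_classes)
    ),
    class = "scenario_spec"
  )
}

#' Apply the hardwood-encroachment transform
#'
#' Converts the centre of each quadrat (a centred square whose area is
#' `converted_fraction` of the quadrat) to the target class, leaving protected
#' classes untouched, and re-derives lichen, cover and edge for converted
#' cells from the class attribute table. Quadrats are anchored at the
#' top-left corner of the grid; partial quadrats at the fringe are handled in
#' quadrat coordinates and clipped.
#'
#' @param grid a [landscape_grid()].
#' @param spec a [scenario_spec()].
#' @return A new `landscape_grid` (the input is unchanged).
#' @export
apply_encroachment <- function(grid, spec = scenario_spec()) {
  s <- grid$cell_size
  q <- as.integer(round(sqrt(spec$quadrat_area * 1e6) / s)) # quadrat side, cells
  if (grid$nrows < 1 || grid$ncols < 1) stop("empty grid", call. = FALSE)
  side <- as.integer(round(sqrt(spec$converted_fraction) * q))
  off <- (q - side) %/% 2L

  sel <- matrix(FALSE, grid$nrows, grid$ncols)
  for (r0 in seq(0L, grid$nrows - 1L, by = q)) {
    for (c0 in seq(0L, grid$ncols - 1L, by = q)) {
      rows <- (r0 + off + 1L):(r0 + off + side)
      cols <- (c0 + off + 1L):(c0 + off + side)
      rows <- rows[rows <= grid$nrows]
      cols <- cols[cols <= grid$ncols]
      sel[rows, cols] <- TRUE
    }
  }
  sel <- sel & !(grid$cover_type %in% spec$protected_classes)

  out <- grid
  out$cover_type[sel] <- spec$target_class
  lut <- grid$landcover
  ti <- match(spec$target_class, lut$class)
  out$lichen[sel] <- lut$lichen[ti]
  out$cover[sel] <- lut$cover[ti]
  out$edge <- derive_edge(out$cover)
  out
}
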