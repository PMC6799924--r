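#' Georeferenced raster grid
#'
#' Minimal single-band raster container used throughout the package: a numeric
#' matrix (row 1 is the northernmost row) plus a geotransform given by the
#' upper-left corner, a square pixel size in metres, and an optional
#' acquisition date. All grids in one analysis are assumed to share a single
#' projected CRS (the study fixes a UTM zone upstream); the package never
#' reprojects.
#'
#' @param values numeric matrix of cell values (row 1 = top).
#' @param xmin x coordinate of the left edge (m).
#' @param ymax y coordinate of the top edge (m).
#' @param pixel pixel size (m), square pixels.
#' @param date optional `Date` (or string coercible to one) stamped on the grid.
#' @return An object of class `rh_grid`.
#' @examples
#' g <- rh_grid(matrix(1:6, 2, 3), xmin = 0, ymax = 2000, pixel = 1000)
#' grid_extent(g)
#' @export
rh_grid <- function(values, xmin = 0, ymax = nrow(values) * pixel,
                    pixel = 1000, date = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.finite(xmin), is.finite(ymax), pixel > 0)
  if (!is.null(date)) date <- as.Date(date)
  structure(
    list(values = values, xmin = xmin, ymax = ymax, pixel = pixel, date = date),
    class = "rh_grid"
  )
}

#' @export
print.rh_grid <- function(x, ...) {
  cat(sprintf("<rh_grid> %d x %d cells, %g m pixels\n",
              nrow(x$values), ncol(x$values), x$pixel))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(x$values) * x$pixel,
              x$ymax - nrow(x$values) * x$pixel, x$ymax))
  if (!is.null(x$date)) cat("  date:  ", format(x$date), "\n")
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  values: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @rdname rh_grid
#' @param g an `rh_grid`.
#' @export
grid_extent <- function(g) {
  c(xmin = g$xmin, xmax = g$xmin + ncol(g$values) * g$pixel,
    ymin = g$ymax - nrow(g$values) * g$pixel, ymax = g$ymax)
}

# TRUE when two grids share shape and geotransform.
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$pixel - b$pixel) < tol
}

# Apply a function elementwise, preserving geometry.
grid_map <- function(g, f) {
  g$values <- f(g$values)
  g
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols`/`nrows`/`xllcorner`/... header
#' followed by rows of values, northernmost row first). `NA` is written as the
#' `NODATA_value`.
#'
#' @param g an [rh_grid].
#' @param path file path.
#' @param date optional date to stamp on the grid when reading.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns an [rh_grid].
#' @export
write_ascii_grid <- function(g, path) {
  v <- g$values
  ext <- grid_extent(g)
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", ext["xmin"]),
    sprintf("yllcorner %.10g", ext["ymin"]),
    sprintf("cellsize %.10g", g$pixel),
    "NODATA_value -9999"
  )
  body <- apply(v, 1L, function(r) {
    r[!is.finite(r)] <- -9999
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, date = NULL) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keyval <- stats::setNames(
    vapply(hdr, function(h) as.numeric(h[2]), 0),
    tolower(vapply(hdr, `[`, "", 1))
  )
  nr <- as.integer(keyval[["nrows"]])
  nc <- as.integer(keyval[["ncols"]])
  vals <- lapply(lines[7:(6 + nr)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  stopifnot(ncol(m) == nc)
  m[m == keyval[["nodata_value"]]] <- NA_real_
  rh_grid(m,
          xmin = keyval[["xllcorner"]],
          ymax = keyval[["yllcorner"]] + nr * keyval[["cellsize"]],
          pixel = keyval[["cellsize"]], date = date)
}

## ---- polygon geometry --------------------------------------------------
## Polygons are two-column matrices of vertices (x, y), implicitly closed.
## Pixel rectangles are convex, so Sutherland-Hodgman clipping against the
## four half-planes of a pixel is exact for any simple polygon.

# Signed area by the shoelace formula; abs() gives the geometric area.
poly_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Clip polygon p (n x 2 matrix) to the axis-aligned rectangle
# [x0,x1] x [y0,y1]; returns a matrix (possibly with 0 rows).
clip_poly_rect <- function(p, x0, x1, y0, y1) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- vector("list", 2L * n)
    m <- 0L
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) { m <- m + 1L; out[[m]] <- intersect(prev, cur) }
        m <- m + 1L; out[[m]] <- cur
      } else if (prev_in) {
        m <- m + 1L; out[[m]] <- intersect(prev, cur)
      }
      prev <- cur; prev_in <- cur_in
    }
    if (m == 0L) return(matrix(numeric(0), 0, 2)) else do.call(rbind, out[seq_len(m)])
  }
  ix <- function(a, b, at, coord) {
    # intersection of segment a-b with the line coord == at
    t <- (at - a[coord]) / (b[coord] - a[coord])
    a + t * (b - a)
  }
  p <- clip_half(p, function(v) v[1] >= x0, function(a, b) ix(a, b, x0, 1))
  p <- clip_half(p, function(v) v[1] <= x1, function(a, b) ix(a, b, x1, 1))
  p <- clip_half(p, function(v) v[2] >= y0, function(a, b) ix(a, b, y0, 2))
  p <- clip_half(p, function(v) v[2] <= y1, function(a, b) ix(a, b, y1, 2))
  p
}

# Rectangle polygon helper (counter-clockwise).
rect_poly <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
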