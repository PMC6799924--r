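#' Nearest-neighbour resampling
#'
#' Resamples a grid to a new pixel size; every output pixel takes the value of
#' the source pixel whose centre is nearest to the output pixel's centre, so
#' the output value set is a subset of the source's (the convention used to
#' bring 1-km RH rasters to 250 m before zonal extraction).
#'
#' @param raster an [rh_grid] (or the `rh_percent` grid of an `rh_raster`).
#' @param target_pixel_m output pixel size in metres (default 250).
#' @return An [rh_grid] at the new resolution covering the same extent.
#' @export
resample_nearest <- function(raster, target_pixel_m = 250) {
  if (inherits(raster, "rh_raster")) raster <- raster$rh_percent
  stopifnot(inherits(raster, "rh_grid"))
  if (target_pixel_m <= 0) stop("target pixel size must be positive")
  src <- raster$values
  ext <- grid_extent(raster)
  nc <- max(1L, as.integer(round((ext["xmax"] - ext["xmin"]) / target_pixel_m)))
  nr <- max(1L, as.integer(round((ext["ymax"] - ext["ymin"]) / target_pixel_m)))
  xc <- raster$xmin + (seq_len(nc) - 0.5) * target_pixel_m
  yc <- raster$ymax - (seq_len(nr) - 0.5) * target_pixel_m
  j <- pmin(pmax(floor((xc - raster$xmin) / raster$pixel) + 1L, 1L), ncol(src))
  i <- pmin(pmax(floor((raster$ymax - yc) / raster$pixel) + 1L, 1L), nrow(src))
  rh_grid(src[i, j, drop = FALSE], xmin = raster$xmin, ymax = raster$ymax,
          pixel = target_pixel_m, date = raster$date)
}

# Exact pixel-in-polygon weights for one block on one grid geometry:
# data.frame(i, j, area) of pixels with positive intersection area (m^2),
# found by clipping the block polygon against each candidate pixel rectangle.
pixel_weights <- function(raster, poly) {
  px <- raster$pixel
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  j0 <- max(1L, floor((bx[1] - raster$xmin) / px) + 1L)
  j1 <- min(ncol(raster$values), ceiling((bx[2] - raster$xmin) / px))
  i0 <- max(1L, floor((raster$ymax - by[2]) / px) + 1L)
  i1 <- min(nrow(raster$values), ceiling((raster$ymax - by[1]) / px))
  if (j1 < j0 || i1 < i0) return(data.frame(i = integer(0), j = integer(0), area = numeric(0)))
  res <- list(); m <- 0L
  for (i in i0:i1) {
    yt <- raster$ymax - (i - 1L) * px
    yb <- yt - px
    for (j in j0:j1) {
      xl <- raster$xmin + (j - 1L) * px
      a <- poly_area(clip_poly_rect(poly, xl, xl + px, yb, yt))
      if (a > 0) { m <- m + 1L; res[[m]] <- c(i, j, a) }
    }
  }
  if (m == 0L) return(data.frame(i = integer(0), j = integer(0), area = numeric(0)))
  out <- do.call(rbind, res)
  data.frame(i = as.integer(out[, 1]), j = as.integer(out[, 2]), area = out[, 3])
}

#' Area-weighted mean of a raster over a block polygon
#'
#' Zonal statistic defined as the sum of (pixel area inside the block x pixel
#' value) divided by the total intersected area. Intersection areas are exact
#' (polygon clipped against each pixel rectangle), not centroid-in-polygon.
#' `NaN`/`NA` pixels are excluded from both sums; if the valid fraction of the
#' block area falls below `min_coverage` the result is `NA` with a warning.
#'
#' @param raster an [rh_grid] or `rh_raster`.
#' @param block polygon as a two-column vertex matrix.
#' @param min_coverage minimum valid-area fraction (default 0.5).
#' @return Scalar weighted mean, with attribute `coverage` (valid-area
#'   fraction of the block).
#' @export
area_weighted_mean <- function(raster, block, min_coverage = 0.5) {
  if (inherits(raster, "rh_raster")) raster <- raster$rh_percent
  w <- pixel_weights(raster, block)
  if (nrow(w) == 0L)
    stop("block does not intersect the raster extent")
  v <- raster$values[cbind(w$i, w$j)]
  ok <- is.finite(v)
  total <- poly_area(block)
  coverage <- sum(w$area[ok]) / total
  val <- if (coverage < min_coverage) {
    warning(sprintf("valid coverage %.2f below %.2f; returning NA",
                    coverage, min_coverage))
    NA_real_
  } else {
    sum(w$area[ok] * v[ok]) / sum(w$area[ok])
  }
  structure(val, coverage = coverage)
}

#' Block-level RH time series from a stack of rasters
#'
#' Computes the area-weighted mean RH of every block for every dated raster.
#' All rasters must share one geometry (the pixel weights per block are
#' computed once and reused).
#'
#' @param rasters list of [rh_grid]s or `rh_raster`s, each with a distinct
#'   `date`.
#' @param layout an [estate_layout].
#' @param min_coverage minimum valid-area fraction per block.
#' @return data.frame of class `block_rh_series` with columns `block_id`,
#'   `date`, `rh`, sorted by block then date.
#' @export
build_block_series <- function(rasters, layout, min_coverage = 0.5) {
  rasters <- lapply(rasters, function(r)
    if (inherits(r, "rh_raster")) r$rh_percent else r)
  stopifnot(length(rasters) > 0L)
  ref <- rasters[[1]]
  dates <- do.call(c, lapply(rasters, function(r) {
    if (is.null(r$date)) stop("every raster needs a date")
    r$date
  }))
  if (anyDuplicated(dates)) stop("duplicate raster dates")
  for (r in rasters) if (!same_geometry(r, ref))
    stop("rasters do not share one geometry (projection/extent mismatch)")
  wts <- lapply(layout$blocks, pixel_weights, raster = ref)
  areas <- vapply(layout$blocks, poly_area, 0)
  res <- vector("list", length(rasters))
  for (t in seq_along(rasters)) {
    v <- rasters[[t]]$values
    rh <- vapply(seq_along(wts), function(b) {
      w <- wts[[b]]
      vv <- v[cbind(w$i, w$j)]
      ok <- is.finite(vv)
      cov <- sum(w$area[ok]) / areas[b]
      if (cov < min_coverage) NA_real_ else sum(w$area[ok] * vv[ok]) / sum(w$area[ok])
    }, 0)
    res[[t]] <- data.frame(block_id = names(layout$blocks),
                           date = dates[t], rh = rh)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$block_id, out$date), ]
  rownames(out) <- NULL
  class(out) <- c("block_rh_series", "data.frame")
  out
}

#' Assemble the lagged predictor table
#'
#' Pairs each census record with the block's mean RH in six trailing windows:
#' lag Tk is the mean of available RH values in the `window_days`-day window
#' ending exactly `7*k` days before the census date (k = 1..6). Rows missing
#' any required lag are dropped and logged.
#'
#' @param series a `block_rh_series` data.frame (`block_id`, `date`, `rh`).
#' @param census a `census_records` data.frame.
#' @param window_days averaging window length in days (default 8).
#' @param required_lags integer lags (1..6) that must be non-missing for a row
#'   to be kept; default all six.
#' @return data.frame of class `lagged_dataset` with columns `block_id`,
#'   `cycle_index`, `census_date`, `mean_count_per_palm`, `rh_T1`..`rh_T6`;
#'   attributes `lag_definition` (days per lag), `window_days` and
#'   `cleaning_log` (data.frame of dropped rows and reasons).
#' @export
assemble_lagged <- function(series, census, window_days = 8L,
                            required_lags = 1:6) {
  if (window_days < 1) stop("window_days must be >= 1")
  if (nrow(census) == 0L) stop("empty census")
  miss <- setdiff(unique(census$block_id), unique(series$block_id))
  if (length(miss))
    stop(sprintf("no RH series for block(s): %s", paste(miss, collapse = ", ")))
  series$date <- as.Date(series$date)
  census$census_date <- as.Date(census$census_date)
  s_split <- split(series, series$block_id)
  lag_cols <- lag_names()
  out <- census
  for (nm in lag_cols) out[[nm]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    b <- s_split[[out$block_id[i]]]
    for (k in 1:6)
      out[[lag_cols[k]]][i] <-
        window_mean(b$date, b$rh, out$census_date[i], 7L * k, window_days)
  }
  need <- lag_cols[required_lags]
  bad <- !stats::complete.cases(out[, c("mean_count_per_palm", need)])
  log <- if (any(bad)) {
    data.frame(block_id = out$block_id[bad],
               census_date = out$census_date[bad],
               reason = "missing value in required column")
  } else {
    data.frame(block_id = character(0), census_date = as.Date(character(0)),
               reason = character(0))
  }
  res <- out[!bad, , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            lag_definition = stats::setNames(7L * (1:6), paste0("T", 1:6)),
            window_days = as.integer(window_days),
            cleaning_log = log,
            class = c("lagged_dataset", "data.frame"))
}

#' Remove anomalous rows from a lagged dataset
#'
#' Mirrors the pre-modelling exclusion of missing values and outliers: rows
#' with missing values are always dropped; additionally the chosen rule flags
#' count outliers — `"zscore3"` (|z| > 3 on the count column, default),
#' `"iqr1.5"` (outside 1.5 IQR fences), or `"none"`.
#'
#' @param ds a `lagged_dataset`.
#' @param outlier_rule `"zscore3"`, `"iqr1.5"` or `"none"`.
#' @return The filtered `lagged_dataset`; the `cleaning_log` attribute gains
#'   one row per removal.
#' @export
clean_dataset <- function(ds, outlier_rule = c("zscore3", "iqr1.5", "none")) {
  outlier_rule <- match.arg(outlier_rule)
  log <- attr(ds, "cleaning_log")
  y <- ds$mean_count_per_palm
  miss <- !stats::complete.cases(as.data.frame(ds))
  out <- rep(FALSE, nrow(ds))
  yy <- y[!miss]
  if (outlier_rule == "zscore3" && length(yy) > 1 && stats::sd(yy) > 0) {
    z <- (y - mean(yy)) / stats::sd(yy)
    out <- !miss & abs(z) > 3
  } else if (outlier_rule == "iqr1.5" && length(yy) > 1) {
    qs <- stats::quantile(yy, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    out <- !miss & (y < qs[1] - 1.5 * iqr | y > qs[2] + 1.5 * iqr)
  }
  drop <- miss | out
  if (any(drop)) {
    nd <- sum(drop)
    log <- rbind(log, data.frame(
      block_id = if (!is.null(ds$block_id)) ds$block_id[drop] else rep(NA_character_, nd),
      census_date = if (!is.null(ds$census_date)) ds$census_date[drop] else rep(as.Date(NA), nd),
      reason = ifelse(miss[drop], "missing value",
                      sprintf("outlier (%s)", outlier_rule))))
  }
  res <- ds[!drop, , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            lag_definition = attr(ds, "lag_definition"),
            window_days = attr(ds, "window_days"),
            cleaning_log = log,
            class = class(ds))
}

#' Write / read a lagged dataset as CSV plus sidecar JSON
#'
#' The CSV holds the rows; the sidecar (`<path>.json`) records the lag
#' definition, window length and the cleaning log.
#'
#' @param ds a `lagged_dataset`.
#' @param path CSV file path.
#' @return `write_lagged_csv` returns `path` invisibly; `read_lagged_csv`
#'   returns a `lagged_dataset`.
#' @export
write_lagged_csv <- function(ds, path) {
  df <- as.data.frame(ds)
  df$census_date <- format(as.Date(df$census_date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  log <- attr(ds, "cleaning_log")
  log$census_date <- format(as.Date(log$census_date), "%Y-%m-%d")
  jsonlite::write_json(
    list(lag_definition = as.list(attr(ds, "lag_definition")),
         window_days = attr(ds, "window_days"),
         cleaning_log = log),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lagged_csv
#' @export
read_lagged_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$census_date <- as.Date(df$census_date)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  log <- as.data.frame(meta$cleaning_log)
  if (nrow(log)) log$census_date <- as.Date(log$census_date)
  structure(df,
            lag_definition = unlist(meta$lag_definition),
            window_days = meta$window_days,
            cleaning_log = log,
            class = c("lagged_dataset", "data.frame"))
}
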