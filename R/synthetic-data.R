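#' Synthetic estate layout
#'
#' Builds the default synthetic study area: a 2000-ha estate of 26 rectangular
#' management blocks in two divisions (A: 10 blocks of 80 ha, B: 16 blocks of
#' 75 ha), embedded with an offset inside a 7 x 6 km raster grid of 1-km
#' pixels so that block edges deliberately straddle pixel boundaries and the
#' area-weighted extraction is exercised with fractional pixel areas.
#'
#' @param pixel raster pixel size in metres (default 1000).
#' @param origin numeric length-2, (xmin, ymax) of the raster grid.
#' @param estate_offset numeric length-2, offset (m) of the estate's
#'   south-west corner from the grid's south-west corner.
#' @return An object of class `estate_layout`: list with `blocks` (named list
#'   of vertex matrices), `division` (named "A"/"B" vector), `area_ha`,
#'   and `grid` (xmin, ymax, pixel, nrow, ncol).
#' @examples
#' lay <- estate_layout()
#' table(lay$division)
#' sum(lay$area_ha)  # 2000 ha
#' @export
estate_layout <- function(pixel = 1000, origin = c(0, 6000),
                          estate_offset = c(730, 610)) {
  nrow_g <- 6L; ncol_g <- 7L
  x0 <- origin[1] + estate_offset[1]
  y0 <- origin[2] - nrow_g * pixel + estate_offset[2]
  blocks <- list(); division <- character(0)
  # Division B: 4 rows x 4 cols of 1250 x 600 m blocks (south strip, 75 ha)
  # Division A: 2 rows x 5 cols of 1000 x 800 m blocks (north strip, 80 ha)
  k <- 0L
  for (r in 1:4) for (cc in 1:4) {
    k <- k + 1L
    id <- sprintf("B%02d", k)
    blocks[[id]] <- rect_poly(x0 + (cc - 1) * 1250, x0 + cc * 1250,
                              y0 + (r - 1) * 600, y0 + r * 600)
    division[id] <- "B"
  }
  yA <- y0 + 2400
  k <- 0L
  for (r in 1:2) for (cc in 1:5) {
    k <- k + 1L
    id <- sprintf("A%02d", k)
    blocks[[id]] <- rect_poly(x0 + (cc - 1) * 1000, x0 + cc * 1000,
                              yA + (r - 1) * 800, yA + r * 800)
    division[id] <- "A"
  }
  area_ha <- vapply(blocks, poly_area, 0) / 1e4
  ext_ok <- vapply(blocks, function(p) {
    all(p[, 1] >= origin[1] & p[, 1] <= origin[1] + ncol_g * pixel &
        p[, 2] >= origin[2] - nrow_g * pixel & p[, 2] <= origin[2])
  }, TRUE)
  stopifnot(all(ext_ok))
  structure(list(blocks = blocks, division = division, area_ha = area_ha,
                 grid = list(xmin = origin[1], ymax = origin[2], pixel = pixel,
                             nrow = nrow_g, ncol = ncol_g)),
            class = "estate_layout")
}

#' @export
print.estate_layout <- function(x, ...) {
  cat(sprintf("<estate_layout> %d blocks (%s), %.0f ha total\n",
              length(x$blocks),
              paste(sprintf("%s: %d", names(table(x$division)),
                            as.integer(table(x$division))), collapse = ", "),
              sum(x$area_ha)))
  cat(sprintf("  raster grid: %d x %d cells of %g m\n",
              x$grid$nrow, x$grid$ncol, x$grid$pixel))
  invisible(x)
}

# Empty grid on the layout geometry filled with `value` (scalar or matrix).
layout_grid <- function(layout, value, date = NULL) {
  g <- layout$grid
  m <- if (is.matrix(value)) {
    stopifnot(nrow(value) == g$nrow, ncol(value) == g$ncol)
    value
  } else {
    matrix(value, g$nrow, g$ncol)
  }
  rh_grid(m, xmin = g$xmin, ymax = g$ymax, pixel = g$pixel, date = date)
}

#' Write / read block polygons as GeoJSON
#'
#' Blocks are serialized as a GeoJSON `FeatureCollection` of `Polygon`
#' features with `block_id`, `division` and `area_ha` properties; coordinates
#' are in the (projected) analysis CRS.
#'
#' @param layout an [estate_layout].
#' @param path file path.
#' @return `write_blocks_geojson` returns `path` invisibly;
#'   `read_blocks_geojson` returns a list with `blocks`, `division`, `area_ha`.
#' @export
write_blocks_geojson <- function(layout, path) {
  feats <- lapply(names(layout$blocks), function(id) {
    p <- layout$blocks[[id]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(block_id = id,
                           division = unname(layout$division[id]),
                           area_ha = unname(layout$area_ha[id])),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blocks_geojson
#' @export
read_blocks_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  blocks <- list(); division <- character(0); area_ha <- numeric(0)
  for (f in fc$features) {
    id <- f$properties$block_id
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    blocks[[id]] <- ring[-nrow(ring), , drop = FALSE]
    division[id] <- f$properties$division
    area_ha[id] <- f$properties$area_ha
  }
  list(blocks = blocks, division = division, area_ha = area_ha)
}

# Positive-branch inversion of each PW variant: returns the Tobs that the
# forward precipitable_water() maps back to `pw`, choosing the root that
# keeps all reflectances positive and within (0, 1.5].
invert_pw <- function(pw, alpha, beta, variant) {
  s <- sqrt(pw)
  switch(variant,
    as_printed_grouped = alpha + beta * s,
    as_printed_literal = beta * (alpha + s),
    log_form = exp(alpha - beta * s))
}

#' Generate a reflectance scene with known true precipitable water
#'
#' Inverts the channel-ratio retrieval: window-band reflectances are set to
#' seeded values near configurable constants, and each absorption-band
#' reflectance is solved from the transmittance that makes the forward chain
#' recover `true_pw` exactly (all three per-band PW estimates equal `true_pw`,
#' so the fused PW does too). Running [derive_rh()] with the same `variant` on
#' the result reproduces `true_pw` — and hence the implied RH — to numerical
#' round-off.
#'
#' @param layout an [estate_layout] supplying the grid geometry.
#' @param true_pw scalar or matrix of true precipitable water (cm), inside the
#'   invertible domain \[0, 11.5\].
#' @param true_ta_celsius scalar or matrix of surface air temperature (deg C,
#'   in (-10, 50)).
#' @param elevation_m scalar or matrix of elevation (m).
#' @param pw_variant PW formula variant, see [precipitable_water()].
#' @param seed integer seed for the window-band jitter.
#' @param rho_window base reflectances for the 865 and 1240 nm window bands.
#' @param jitter half-width of the uniform window-band jitter.
#' @param date optional acquisition date.
#' @return An [rh_scene].
#' @export
generate_scene <- function(layout, true_pw, true_ta_celsius, elevation_m,
                           pw_variant = c("as_printed_grouped",
                                          "as_printed_literal", "log_form"),
                           seed = 1L, rho_window = c(0.45, 0.40),
                           jitter = 0.03, date = NULL) {
  pw_variant <- match.arg(pw_variant)
  g <- layout$grid
  expand <- function(v, what) {
    m <- if (is.matrix(v)) v else matrix(v, g$nrow, g$ncol)
    if (!all(dim(m) == c(g$nrow, g$ncol)))
      stop(sprintf("grid shape mismatch for %s", what))
    m
  }
  pw <- expand(true_pw, "true_pw")
  ta <- expand(true_ta_celsius, "true_ta_celsius")
  el <- expand(elevation_m, "elevation_m")
  if (any(pw < 0 | pw > 11.5, na.rm = TRUE))
    stop("true_pw outside the invertible domain [0, 11.5]")
  if (any(ta <= -10 | ta >= 50, na.rm = TRUE))
    stop("true_ta_celsius outside the plausible range (-10, 50)")
  coeffs <- rh_coefficients()
  n <- g$nrow * g$ncol
  wb <- with_seed(seed, list(
    w865 = matrix(rho_window[1] + stats::runif(n, -jitter, jitter), g$nrow, g$ncol),
    w1240 = matrix(rho_window[2] + stats::runif(n, -jitter, jitter), g$nrow, g$ncol)
  ))
  t17 <- invert_pw(pw, coeffs$alpha[1], coeffs$beta[1], pw_variant)
  t18 <- invert_pw(pw, coeffs$alpha[2], coeffs$beta[2], pw_variant)
  t19 <- invert_pw(pw, coeffs$alpha[3], coeffs$beta[3], pw_variant)
  den19 <- coeffs$c1 * wb$w865 + coeffs$c2 * wb$w1240
  mk <- function(v) layout_grid(layout, v, date = date)
  rh_scene(rho_865 = mk(wb$w865), rho_1240 = mk(wb$w1240),
           rho_905 = mk(t17 * wb$w865), rho_936 = mk(t18 * wb$w865),
           rho_940 = mk(t19 * den19),
           ta_celsius = mk(ta), elevation_m = mk(el), date = date)
}

#' Precipitable water implied by a target relative humidity
#'
#' Inverts the thermodynamic half of the retrieval: given a target RH (%),
#' air temperature (deg C) and elevation (m), returns the precipitable water
#' (cm) whose forward chain (specific humidity, air pressure, vapour
#' pressures) yields exactly that RH. Used by the scene simulator to plant
#' known RH fields. The quadratic PW-to-Q calibration is inverted on its
#' monotone branch (the root below the vertex at ~11.5 cm).
#'
#' @param rh_percent target RH (%).
#' @param ta_celsius air temperature (deg C).
#' @param elevation_m elevation (m).
#' @return PW (cm). Errors if the target RH is outside the invertible range
#'   for the given temperature and elevation.
#' @export
pw_for_rh <- function(rh_percent, ta_celsius, elevation_m = 0) {
  es_hpa <- saturation_vapour_pressure(ta_celsius, unit = "hPa")
  pa <- air_pressure(elevation_m)
  e <- rh_percent / 100 * es_hpa
  q1000 <- 1000 * 0.622 * e / pa  # 1000*Q, the calibration polynomial's scale
  # solve -0.0762 PW^2 + 1.753 PW + 12.405 = q1000, lower root
  disc <- 1.753^2 - 4 * 0.0762 * (q1000 - 12.405)
  if (any(disc < 0 | q1000 < 12.405, na.rm = TRUE))
    stop("target RH outside the invertible PW domain for this Ta/elevation")
  pw <- (1.753 - sqrt(disc)) / (2 * 0.0762)
  pw
}

# Invertible RH range (%) at a given Ta/elevation: RH implied by PW = 0 and
# PW = 11.5. Used to clamp simulated target fields.
rh_invertible_range <- function(ta_celsius, elevation_m = 0) {
  es_hpa <- saturation_vapour_pressure(ta_celsius, unit = "hPa")
  pa <- air_pressure(elevation_m)
  e_at <- function(pw) specific_humidity(pw) * pa / 0.622
  c(low = 100 * e_at(0) / es_hpa, high = 100 * e_at(11.5) / es_hpa)
}

#' Census response specification
#'
#' Describes how synthetic bagworm counts respond to lag-weighted relative
#' humidity. The deterministic response is `shape(z)` where
#' `z = sum_k w_k * RH_Tk`; Gaussian noise is added and the result clamped to
#' `[count_floor, count_cap]` (the study area's observed 0-32 larvae-per-frond
#' range).
#'
#' Default shape is a peaked quadratic centred at 59% RH with half-width 8
#' percentage points and peak 32, acting on T1-T3 weights (0.45, 0.35, 0.20):
#' a humid-optimum response in the recent lags, nonlinear in every individual
#' lag.
#'
#' @param lag_weights named numeric, weights for T1..T6.
#' @param response_shape `"linear"`, `"quadratic"` (peaked) or `"saturating"`
#'   (logistic in z).
#' @param response_params shape parameters; `NULL` picks shape defaults
#'   calibrated so RH in 47-71% spans counts 0-32.
#' @param noise_sd Gaussian noise standard deviation (counts), default 2.
#' @param count_floor,count_cap clamp bounds, defaults 0 and 32.
#' @param seed RNG seed for the noise.
#' @return A list of class `response_spec` with a `response` function field.
#' @export
response_spec <- function(lag_weights = c(T1 = 0.45, T2 = 0.35, T3 = 0.20,
                                          T4 = 0, T5 = 0, T6 = 0),
                          response_shape = c("quadratic", "linear", "saturating"),
                          response_params = NULL,
                          noise_sd = 2, count_floor = 0, count_cap = 32,
                          seed = 1L) {
  response_shape <- match.arg(response_shape)
  stopifnot(noise_sd >= 0, count_cap > count_floor)
  w <- stats::setNames(numeric(6), paste0("T", 1:6))
  w[names(lag_weights)] <- lag_weights
  p <- response_params %||% switch(response_shape,
    linear = list(a = -188 / 3, b = 4 / 3),        # 0 at RH 47, 32 at RH 71
    quadratic = list(peak = count_cap, center = 59, halfwidth = 8),
    saturating = list(cap = count_cap, mid = 59, scale = 3))
  response <- switch(response_shape,
    linear = function(z) p$a + p$b * z,
    quadratic = function(z) p$peak * (1 - ((z - p$center) / p$halfwidth)^2),
    saturating = function(z) p$cap / (1 + exp(-(z - p$mid) / p$scale)))
  structure(list(lag_weights = w, response_shape = response_shape,
                 response_params = p, response = response,
                 noise_sd = noise_sd, count_floor = count_floor,
                 count_cap = count_cap, seed = as.integer(seed)),
            class = "response_spec")
}

# Mean of series values whose dates fall in the window of `window_days`
# days ENDING exactly `lag_days` before `end_date`. NA when no value falls
# in the window. Shared by the census generator and assemble_lagged so the
# generator's truth and the assembled predictors use one convention.
window_mean <- function(dates, values, end_date, lag_days, window_days) {
  hi <- end_date - lag_days
  lo <- hi - (window_days - 1L)
  sel <- dates >= lo & dates <= hi & is.finite(values)
  if (!any(sel)) return(NA_real_)
  mean(values[sel])
}

#' Generate a synthetic block-level census
#'
#' One record per block per biweekly cycle on a fixed 14-day calendar starting
#' at `epoch`. Counts follow the [response_spec()] applied to the lag-weighted
#' RH computed from `rh_by_block_and_date` with the same windowing convention
#' as [assemble_lagged()] (windows of `window_days` ending 7k days before the
#' census date).
#'
#' @param layout an [estate_layout].
#' @param rh_by_block_and_date data.frame with columns `block_id`, `date`
#'   (Date), `rh` covering every lag window needed.
#' @param spec a [response_spec()].
#' @param cycles_per_year census cycles per year (default 24, biweekly).
#' @param years number of years (default 2).
#' @param epoch first census date.
#' @param window_days lag-averaging window length (default 8).
#' @return data.frame of class `census_records` with columns `block_id`,
#'   `cycle_index`, `census_date`, `mean_count_per_palm`.
#' @export
generate_census <- function(layout, rh_by_block_and_date, spec = response_spec(),
                            cycles_per_year = 24L, years = 2L,
                            epoch = as.Date("2014-03-01"), window_days = 8L) {
  stopifnot(inherits(spec, "response_spec"))
  epoch <- as.Date(epoch)
  n_cycles <- as.integer(cycles_per_year) * as.integer(years)
  dates <- epoch + 14L * (seq_len(n_cycles) - 1L)
  rh <- rh_by_block_and_date
  rh$date <- as.Date(rh$date)
  needed <- which(spec$lag_weights != 0)
  block_ids <- names(layout$blocks)
  out <- expand.grid(block_id = block_ids, cycle_index = seq_len(n_cycles),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$census_date <- dates[out$cycle_index]
  z <- numeric(nrow(out))
  rh_split <- split(rh, rh$block_id)
  for (i in seq_len(nrow(out))) {
    b <- rh_split[[out$block_id[i]]]
    zi <- 0
    for (k in needed) {
      m <- window_mean(b$date, b$rh, out$census_date[i], 7L * k, window_days)
      if (is.na(m))
        stop(sprintf("missing RH coverage for block %s, lag T%d, census %s",
                     out$block_id[i], k, format(out$census_date[i])))
      zi <- zi + spec$lag_weights[k] * m
    }
    z[i] <- zi
  }
  det <- spec$response(z)
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, stats::rnorm(nrow(out), 0, spec$noise_sd))
  else 0
  out$mean_count_per_palm <- pmin(pmax(det + noise, spec$count_floor),
                                  spec$count_cap)
  class(out) <- c("census_records", "data.frame")
  out
}

#' Per-palm counts consistent with a block average
#'
#' Draws the 25 individual palm counts behind one block-level census figure:
#' non-negative integers from a Poisson distribution with the block mean as
#' intensity. Averaging the returned counts reproduces the block-averaging
#' convention (total over palms / number of palms).
#'
#' @param block_mean target block average (>= 0).
#' @param n_palms number of palms sampled per block (default 25).
#' @param seed RNG seed.
#' @return Integer vector of length `n_palms`.
#' @export
generate_palm_level_census <- function(block_mean, n_palms = 25L, seed = 1L) {
  if (block_mean < 0) stop("block_mean must be non-negative")
  with_seed(seed, stats::rpois(n_palms, block_mean))
}

#' Simulate block-level daily RH series
#'
#' Daily relative-humidity series for every block: a shared seasonal sine, a
#' shared AR(1) day-to-day component, a per-block offset and per-block daily
#' noise, clamped to `range`. Emulates the humid-tropics regime the estate
#' sits in (RH roughly 47-71%); it does not emulate cloud-induced gaps.
#'
#' @param layout an [estate_layout] (or character vector of block ids).
#' @param dates Date vector (consecutive days recommended).
#' @param seed RNG seed.
#' @param mean long-run mean RH (%).
#' @param seasonal_amp amplitude of the annual sine (%).
#' @param ar_phi,ar_sd AR(1) coefficient and innovation SD of the shared
#'   day-to-day component.
#' @param block_sd SD of the static per-block offsets.
#' @param daily_sd SD of independent per-block daily noise.
#' @param range clamp range for RH (%).
#' @return data.frame with columns `block_id`, `date`, `rh`.
#' @export
simulate_block_rh <- function(layout, dates, seed = 1L, mean = 59,
                              seasonal_amp = 4, ar_phi = 0.6, ar_sd = 4,
                              block_sd = 1.5, daily_sd = 1,
                              range = c(47, 71)) {
  block_ids <- if (inherits(layout, "estate_layout")) names(layout$blocks)
               else as.character(layout)
  dates <- as.Date(dates)
  nd <- length(dates); nb <- length(block_ids)
  with_seed(seed, {
    doy <- as.numeric(dates - min(dates))
    seasonal <- seasonal_amp * sin(2 * pi * doy / 365 + stats::runif(1, 0, 2 * pi))
    ar <- numeric(nd)
    ar[1] <- stats::rnorm(1, 0, ar_sd / sqrt(1 - ar_phi^2))
    if (nd > 1) for (t in 2:nd)
      ar[t] <- ar_phi * ar[t - 1] + stats::rnorm(1, 0, ar_sd)
    offs <- stats::rnorm(nb, 0, block_sd)
    noise <- matrix(stats::rnorm(nd * nb, 0, daily_sd), nd, nb)
    rh <- outer(mean + seasonal + ar, rep(1, nb)) +
      outer(rep(1, nd), offs) + noise
    rh <- pmin(pmax(rh, range[1]), range[2])
    data.frame(block_id = rep(block_ids, each = nd),
               date = rep(dates, nb),
               rh = as.vector(rh))
  })
}

#' Write / read census tables as CSV
#'
#' @param census a `census_records` data.frame.
#' @param path file path.
#' @return `write_census_csv` returns `path` invisibly; `read_census_csv`
#'   returns a `census_records` data.frame.
#' @export
write_census_csv <- function(census, path) {
  df <- census
  df$census_date <- format(as.Date(df$census_date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$census_date <- as.Date(df$census_date)
  class(df) <- c("census_records", "data.frame")
  df
}
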