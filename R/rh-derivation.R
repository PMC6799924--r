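#' Transmittance and water-vapour fusion coefficients
#'
#' Registry of the constants used by the NIR channel-ratio retrieval, with the
#' Malaysian-calibration defaults: per-band transmittance coefficients
#' (alpha, beta) for the three absorption bands (0.905, 0.936, 0.940 um),
#' the window-band mixing constants C1, C2 used in the band-19 ratio, and the
#' fusion weights f1, f2, f3 that average the three per-band precipitable
#' water estimates.
#'
#' @param alpha,beta length-3 numeric, one entry per absorption band
#'   (905, 936, 940 nm).
#' @param c1,c2 window-band mixing constants for the 940 nm ratio.
#' @param f length-3 fusion weights; must sum to 1.
#' @return A list of class `rh_coefficients`.
#' @examples
#' rh_coefficients()
#' @export
rh_coefficients <- function(alpha = c(b17 = 0.025, b18 = 0.056, b19 = 0.120),
                            beta  = c(b17 = 0.30,  b18 = 0.60,  b19 = 0.651),
                            c1 = 0.8, c2 = 0.2,
                            f = c(f1 = 0.36, f2 = 0.24, f3 = 0.40)) {
  stopifnot(length(alpha) == 3L, length(beta) == 3L, length(f) == 3L)
  if (abs(sum(f) - 1) > 1e-6)
    stop("fusion weights f must sum to 1 (deviation > 1e-6)")
  structure(list(alpha = alpha, beta = beta, c1 = c1, c2 = c2, f = f),
            class = "rh_coefficients")
}

#' @export
print.rh_coefficients <- function(x, ...) {
  cat("<rh_coefficients>\n")
  cat(sprintf("  band %s: alpha = %g, beta = %g\n",
              c("17 (0.905um)", "18 (0.936um)", "19 (0.940um)"),
              x$alpha, x$beta), sep = "")
  cat(sprintf("  C1 = %g, C2 = %g;  f = (%g, %g, %g)\n",
              x$c1, x$c2, x$f[1], x$f[2], x$f[3]))
  invisible(x)
}

#' Co-registered reflectance scene
#'
#' Bundles the five NIR apparent-reflectance grids (window bands at 865 and
#' 1240 nm; absorption bands at 905, 936, 940 nm), a surface air temperature
#' grid (deg C) and an elevation grid (m) that share one geotransform.
#'
#' @param rho_865,rho_1240,rho_905,rho_936,rho_940 [rh_grid]s of apparent
#'   reflectance (dimensionless, in (0, 1.5]).
#' @param ta_celsius [rh_grid] of surface air temperature (deg C).
#' @param elevation_m [rh_grid] of elevation (m).
#' @param date optional acquisition `Date`.
#' @return An object of class `rh_scene`.
#' @export
rh_scene <- function(rho_865, rho_1240, rho_905, rho_936, rho_940,
                     ta_celsius, elevation_m, date = NULL) {
  grids <- list(rho_865 = rho_865, rho_1240 = rho_1240, rho_905 = rho_905,
                rho_936 = rho_936, rho_940 = rho_940,
                ta_celsius = ta_celsius, elevation_m = elevation_m)
  ref <- grids[[1]]
  for (nm in names(grids)) {
    if (!inherits(grids[[nm]], "rh_grid"))
      stop(sprintf("'%s' must be an rh_grid", nm))
    if (!same_geometry(grids[[nm]], ref))
      stop(sprintf("grid '%s' does not share the scene geotransform/shape", nm))
  }
  for (nm in c("rho_865", "rho_1240", "rho_905", "rho_936", "rho_940")) {
    v <- grids[[nm]]$values
    bad <- v[is.finite(v)]
    if (length(bad) && (any(bad <= 0) || any(bad > 1.5)))
      stop(sprintf("reflectance '%s' outside (0, 1.5]", nm))
  }
  structure(c(grids, list(date = if (is.null(date)) ref$date else as.Date(date))),
            class = "rh_scene")
}

#' @export
print.rh_scene <- function(x, ...) {
  cat(sprintf("<rh_scene> %d x %d cells", nrow(x$rho_865$values),
              ncol(x$rho_865$values)))
  if (!is.null(x$date)) cat(", date", format(x$date))
  cat("\n  bands: rho 865/1240/905/936/940 nm, Ta (degC), elevation (m)\n")
  invisible(x)
}

#' Observed transmittance from channel ratios
#'
#' Ratios each absorption-band apparent reflectance to the window band(s):
#' `Tobs17 = rho(905)/rho(865)`, `Tobs18 = rho(936)/rho(865)`,
#' `Tobs19 = rho(940) / (C1*rho(865) + C2*rho(1240))`.
#' Pixels whose denominator is zero yield `NaN` and are counted in the
#' `n_bad` attribute.
#'
#' @param scene an [rh_scene].
#' @param coeffs an [rh_coefficients] (supplies C1, C2).
#' @return A list of three [rh_grid]s (`tobs_17`, `tobs_18`, `tobs_19`) with an
#'   `n_bad` attribute giving the count of zero-denominator pixels.
#' @export
observed_transmittance <- function(scene, coeffs = rh_coefficients()) {
  w865 <- scene$rho_865$values
  w1240 <- scene$rho_1240$values
  den19 <- coeffs$c1 * w865 + coeffs$c2 * w1240
  safe_ratio <- function(num, den) {
    out <- num / den
    out[den == 0] <- NaN
    out
  }
  t17 <- safe_ratio(scene$rho_905$values, w865)
  t18 <- safe_ratio(scene$rho_936$values, w865)
  t19 <- safe_ratio(scene$rho_940$values, den19)
  n_bad <- sum(w865 == 0, na.rm = TRUE) * 2L + sum(den19 == 0, na.rm = TRUE)
  mk <- function(v) rh_grid(v, scene$rho_865$xmin, scene$rho_865$ymax,
                            scene$rho_865$pixel, scene$date)
  structure(list(tobs_17 = mk(t17), tobs_18 = mk(t18), tobs_19 = mk(t19)),
            n_bad = n_bad)
}

#' Precipitable water from observed transmittance
#'
#' Converts an observed-transmittance grid into precipitable water (cm) with
#' one absorption band's coefficients. The printed source formula,
#' `PW = (alpha - (Tobs)/beta)^2`, is ambiguous about grouping and differs
#' from the logarithmic form common in the channel-ratio literature, so three
#' variants are provided and the choice is recorded on the result:
#' \describe{
#'   \item{`as_printed_grouped`}{`PW = ((alpha - Tobs)/beta)^2` (default)}
#'   \item{`as_printed_literal`}{`PW = (alpha - Tobs/beta)^2`}
#'   \item{`log_form`}{`PW = ((alpha - ln(Tobs))/beta)^2`}
#' }
#'
#' @param tobs [rh_grid] (or numeric) of observed transmittance.
#' @param alpha,beta transmittance coefficients for the band.
#' @param variant one of `"as_printed_grouped"`, `"as_printed_literal"`,
#'   `"log_form"`.
#' @return Grid (or numeric) of PW >= 0, with attribute `pw_variant`.
#' @examples
#' precipitable_water(0.5, alpha = 0.025, beta = 0.30)  # ((0.025-0.5)/0.3)^2
#' @export
precipitable_water <- function(tobs, alpha, beta,
                               variant = c("as_printed_grouped",
                                           "as_printed_literal",
                                           "log_form")) {
  variant <- match.arg(variant)
  f <- function(v) {
    switch(variant,
      as_printed_grouped = ((alpha - v) / beta)^2,
      as_printed_literal = (alpha - v / beta)^2,
      log_form = {
        if (any(v <= 0, na.rm = TRUE))
          stop("log_form requires strictly positive Tobs")
        ((alpha - log(v)) / beta)^2
      })
  }
  out <- if (inherits(tobs, "rh_grid")) grid_map(tobs, f) else f(tobs)
  attr(out, "pw_variant") <- variant
  out
}

#' Fuse per-band precipitable water estimates
#'
#' Pixelwise weighted mean `f1*PW17 + f2*PW18 + f3*PW19` with the calibration
#' weights; the weights must sum to 1 so the fusion is convex.
#'
#' @param pw17,pw18,pw19 conformable [rh_grid]s (or numerics) of PW.
#' @param coeffs an [rh_coefficients] supplying the weights.
#' @return Fused PW, same container type as the inputs.
#' @export
fuse_pw <- function(pw17, pw18, pw19, coeffs = rh_coefficients()) {
  f <- coeffs$f
  if (abs(sum(f) - 1) > 1e-6) stop("fusion weights must sum to 1")
  if (inherits(pw17, "rh_grid")) {
    stopifnot(same_geometry(pw17, pw18), same_geometry(pw17, pw19))
    out <- pw17
    out$values <- f[1] * pw17$values + f[2] * pw18$values + f[3] * pw19$values
    out
  } else {
    unname(f[1] * pw17 + f[2] * pw18 + f[3] * pw19)
  }
}

#' Specific humidity from precipitable water
#'
#' Quadratic calibration `Q = 0.001 * (-0.0762 PW^2 + 1.753 PW + 12.405)`
#' (Q in kg/kg, PW in cm). The quadratic peaks near PW = 11.5 cm; beyond the
#' vertex it would decrease, so PW outside `valid` is mapped to `NaN` with a
#' warning rather than extrapolated.
#'
#' @param pw grid or numeric of PW (cm).
#' @param valid validity interval for PW, default `c(0, 11.5)`.
#' @return Q (kg/kg), same container type.
#' @examples
#' specific_humidity(0)  # 0.012405
#' @export
specific_humidity <- function(pw, valid = c(0, 11.5)) {
  f <- function(v) {
    out <- 0.001 * (-0.0762 * v^2 + 1.753 * v + 12.405)
    bad <- is.finite(v) & (v < valid[1] | v > valid[2])
    if (any(bad)) {
      warning(sprintf("%d PW value(s) outside [%g, %g] set to NaN",
                      sum(bad), valid[1], valid[2]))
      out[bad] <- NaN
    }
    out
  }
  if (inherits(pw, "rh_grid")) grid_map(pw, f) else f(pw)
}

#' Air pressure from elevation
#'
#' Linear barometric approximation `Pa = 1013.3 - 0.1038 * H` (hPa, H in m).
#'
#' @param elevation_m grid or numeric elevation (m); values below `floor_m`
#'   are truncated to it.
#' @param floor_m elevation floor, default 0 m.
#' @return Air pressure (hPa), same container type.
#' @examples
#' air_pressure(0)     # 1013.3
#' air_pressure(1000)  # 909.5
#' @export
air_pressure <- function(elevation_m, floor_m = 0) {
  f <- function(h) 1013.3 - 0.1038 * pmax(h, floor_m)
  if (inherits(elevation_m, "rh_grid")) grid_map(elevation_m, f) else f(elevation_m)
}

#' Vapour pressure from specific humidity and air pressure
#'
#' `e = Q * Pa / 0.622`; e inherits the pressure unit of `Pa` (hPa here).
#'
#' @param q grid or numeric specific humidity (kg/kg).
#' @param pa grid or numeric air pressure (hPa).
#' @return Vapour pressure, same container type.
#' @export
vapour_pressure <- function(q, pa) {
  if (inherits(q, "rh_grid")) {
    stopifnot(same_geometry(q, pa))
    out <- q
    out$values <- q$values * pa$values / 0.622
    out
  } else {
    q * pa / 0.622
  }
}

#' Saturation vapour pressure from air temperature
#'
#' Magnus-type formula `es = 611 * exp(17.27 * Ta / (237.3 + Ta))`, which
#' yields pascals (611 Pa at 0 deg C). Because vapour pressure upstream is in
#' hPa, `unit = "hPa"` (the default used inside [derive_rh()]) divides by 100
#' so that the RH ratio is unit-consistent.
#'
#' @param ta_celsius grid or numeric air temperature (deg C, > -237.3).
#' @param unit `"Pa"` or `"hPa"`.
#' @return Saturation vapour pressure, same container type.
#' @examples
#' saturation_vapour_pressure(0)            # 611 Pa
#' saturation_vapour_pressure(0, "hPa")     # 6.11 hPa
#' @export
saturation_vapour_pressure <- function(ta_celsius, unit = c("Pa", "hPa")) {
  unit <- match.arg(unit)
  f <- function(ta) {
    den <- 237.3 + ta
    out <- 611 * exp(17.27 * ta / den)
    out[is.finite(ta) & den <= 0] <- NaN
    if (unit == "hPa") out / 100 else out
  }
  if (inherits(ta_celsius, "rh_grid")) grid_map(ta_celsius, f) else f(ta_celsius)
}

#' Relative humidity from vapour pressures
#'
#' `RH = 100 * e / es`, optionally clamped into \[0, 100\]. When clamping, the
#' raw (unclamped) values are kept in the `rh_raw` field.
#'
#' @param e,es conformable grids (or numerics) in the SAME pressure unit.
#' @param clamp clamp RH into \[0, 100\]? Default `TRUE`.
#' @return An object of class `rh_raster`: list with `rh_percent` ([rh_grid]
#'   or numeric), `rh_raw`, and provenance fields. For numeric input the
#'   `rh_percent` element is a plain vector.
#' @export
relative_humidity <- function(e, es, clamp = TRUE) {
  ratio <- function(ev, esv) {
    out <- 100 * ev / esv
    out[esv == 0] <- NaN
    out
  }
  if (inherits(e, "rh_grid")) {
    stopifnot(same_geometry(e, es))
    raw <- e
    raw$values <- ratio(e$values, es$values)
    clamped <- raw
    if (clamp) clamped$values <- pmin(pmax(clamped$values, 0), 100)
    structure(list(rh_percent = clamped, rh_raw = raw, clamp = clamp,
                   intermediates = NULL, pw_variant = NULL),
              class = "rh_raster")
  } else {
    raw <- ratio(e, es)
    structure(list(rh_percent = if (clamp) pmin(pmax(raw, 0), 100) else raw,
                   rh_raw = raw, clamp = clamp,
                   intermediates = NULL, pw_variant = NULL),
              class = "rh_raster")
  }
}

#' @export
print.rh_raster <- function(x, ...) {
  cat("<rh_raster>", if (x$clamp) "(clamped to [0,100])" else "(unclamped)",
      if (!is.null(x$pw_variant)) sprintf("pw_variant = %s", x$pw_variant), "\n")
  print(x$rh_percent)
  invisible(x)
}

#' Derive a relative-humidity raster from a reflectance scene
#'
#' Full retrieval chain: channel-ratio observed transmittances, per-band
#' precipitable water, weight fusion, specific humidity, elevation-based air
#' pressure, vapour pressure, Magnus saturation vapour pressure (converted to
#' hPa), and finally `RH = 100 e/es`.
#'
#' @param scene an [rh_scene].
#' @param coeffs an [rh_coefficients].
#' @param variant PW formula variant, see [precipitable_water()].
#' @param clamp clamp RH into \[0, 100\]? Default `TRUE`.
#' @param keep_intermediates retain Tobs, PW, Q, Pa, e, es grids on the result?
#' @param pw_valid validity interval passed to [specific_humidity()].
#' @return An `rh_raster` whose `rh_percent` is an [rh_grid]; provenance fields
#'   record the variant, coefficients and clamp flag.
#' @examples
#' lay <- estate_layout()
#' sc <- generate_scene(lay, true_pw = 3, true_ta_celsius = 30,
#'                      elevation_m = 50, seed = 1)
#' rh <- derive_rh(sc)
#' range(rh$rh_percent$values)
#' @export
derive_rh <- function(scene, coeffs = rh_coefficients(),
                      variant = c("as_printed_grouped", "as_printed_literal",
                                  "log_form"),
                      clamp = TRUE, keep_intermediates = FALSE,
                      pw_valid = c(0, 11.5)) {
  variant <- match.arg(variant)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_stage(stage, conditionMessage(e)))
  }
  tobs <- run("observed_transmittance", observed_transmittance(scene, coeffs))
  pw17 <- run("precipitable_water",
              precipitable_water(tobs$tobs_17, coeffs$alpha[1], coeffs$beta[1], variant))
  pw18 <- run("precipitable_water",
              precipitable_water(tobs$tobs_18, coeffs$alpha[2], coeffs$beta[2], variant))
  pw19 <- run("precipitable_water",
              precipitable_water(tobs$tobs_19, coeffs$alpha[3], coeffs$beta[3], variant))
  pw <- run("fuse_pw", fuse_pw(pw17, pw18, pw19, coeffs))
  q  <- run("specific_humidity", specific_humidity(pw, valid = pw_valid))
  pa <- run("air_pressure", air_pressure(scene$elevation_m))
  e  <- run("vapour_pressure", vapour_pressure(q, pa))
  es <- run("saturation_vapour_pressure",
            saturation_vapour_pressure(scene$ta_celsius, unit = "hPa"))
  out <- run("relative_humidity", relative_humidity(e, es, clamp = clamp))
  out$pw_variant <- variant
  out$coefficients <- coeffs
  if (keep_intermediates)
    out$intermediates <- list(tobs = tobs, pw17 = pw17, pw18 = pw18,
                              pw19 = pw19, pw = pw, q = q, pa = pa,
                              e = e, es = es)
  out
}
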