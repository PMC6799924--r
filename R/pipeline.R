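#' Pipeline configuration
#'
#' Assembles and validates every knob of the end-to-end analysis: the estate
#' layout, simulation span, RH retrieval options, lag-window options,
#' cleaning rule, the nine predictor configurations (each single lag T1..T6,
#' the two multi-lag sets T1-T3 and T4-T6, and automatic selection), and the
#' network training configuration. Unknown arguments are rejected.
#'
#' @param out_dir output directory for the run.
#' @param seed root seed; every stage derives its own child seed from it.
#' @param layout an [estate_layout].
#' @param years,cycles_per_year census calendar (defaults 2 and 24).
#' @param epoch first census date.
#' @param pw_variant PW formula variant for both simulation and retrieval.
#' @param clamp clamp RH into \[0, 100\]?
#' @param target_pixel_m resampling target (default 250 m).
#' @param window_days lag-averaging window (default 8).
#' @param cleaning_rule `"zscore3"`, `"iqr1.5"` or `"none"`.
#' @param response a [response_spec()] driving the synthetic census.
#' @param train a [train_config()] for the networks.
#' @param hidden_range hidden sizes searched per network configuration.
#' @param ... rejected; catches misspelled options.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("bagworm_run_"),
                            seed = 1L,
                            layout = estate_layout(),
                            years = 2L, cycles_per_year = 24L,
                            epoch = as.Date("2014-03-01"),
                            pw_variant = "as_printed_grouped",
                            clamp = TRUE,
                            target_pixel_m = 250,
                            window_days = 8L,
                            cleaning_rule = "zscore3",
                            response = NULL,
                            train = NULL,
                            hidden_range = 1:10,
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(names(extra), collapse = ", ")))
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), layout = layout,
              years = as.integer(years),
              cycles_per_year = as.integer(cycles_per_year),
              epoch = as.Date(epoch), pw_variant = pw_variant, clamp = clamp,
              target_pixel_m = target_pixel_m,
              window_days = as.integer(window_days),
              cleaning_rule = cleaning_rule,
              response = response %||% response_spec(seed = child_seed(seed, 3)),
              train = train %||% train_config(seed = child_seed(seed, 4)),
              hidden_range = hidden_range,
              model_configs = c(lapply(1:6, identity),
                                list(1:3, 4:6, "auto")))
  names(cfg$model_configs) <- c(paste0("T", 1:6), "T1,T2,T3", "T4,T5,T6",
                                "stepwise")
  structure(cfg, class = "pipeline_config")
}

# Simulate one day's true RH field plus its temperature: day-level mean from
# a seasonal sine + AR(1) walk, a fixed east-west gradient, and pixel noise;
# temperature anti-correlates with the day's humidity (hot afternoons are
# dry), which also keeps the target RH inside the invertible PW domain.
simulate_day_state <- function(layout, day_index, ar_value, seed) {
  g <- layout$grid
  m_d <- 59 + 4 * sin(2 * pi * day_index / 365) + ar_value
  ta <- 44 - 0.22 * m_d
  grad <- matrix(rep(seq(-2, 2, length.out = g$ncol), each = g$nrow),
                 g$nrow, g$ncol)
  noise <- with_seed(seed,
                     matrix(stats::rnorm(g$nrow * g$ncol, 0, 1), g$nrow, g$ncol))
  rng <- rh_invertible_range(ta, 40)
  rh <- pmin(pmax(m_d + grad + noise, rng["low"] + 0.5), rng["high"] - 0.5)
  rh <- pmin(pmax(rh, 47), 71)
  list(rh = rh, ta = ta)
}

#' Run the full analysis pipeline
#'
#' Executes every stage end to end on synthetic inputs: simulate daily
#' reflectance scenes with known true RH, derive RH rasters, resample to the
#' extraction resolution, build block RH series by area-weighted means,
#' generate the synthetic census from the response specification, assemble
#' and clean the lagged dataset, split it, fit linear and polynomial
#' regressions and a quickprop MLP for each of the nine predictor
#' configurations, and evaluate everything. Outputs (lagged dataset CSV,
#' model JSONs, comparison CSVs, run manifest) are written under
#' `config$out_dir`; the fitted objects are returned. Fully deterministic
#' given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages?
#' @return Invisibly, a list with `series`, `census`, `dataset`, `splits`,
#'   `models` (per configuration: `linear`, `polynomial`, `ann`),
#'   `comparison` (Table-3-style adjusted R-squared data.frame), `ann_report`
#'   (Table-4-style errors/accuracies) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- config$layout

  ## stage 1: simulate scenes and derive RH rasters
  n_cycles <- config$cycles_per_year * config$years
  census_dates <- config$epoch + 14L * (seq_len(n_cycles) - 1L)
  rh_dates <- seq(config$epoch - 49L, max(census_dates), by = "1 day")
  nd <- length(rh_dates)
  say("simulate/derive: %d daily scenes on a %dx%d grid", nd,
      layout$grid$nrow, layout$grid$ncol)
  ar <- with_seed(child_seed(config$seed, 1), {
    v <- numeric(nd)
    v[1] <- stats::rnorm(1, 0, 3 / sqrt(1 - 0.36))
    if (nd > 1) for (t in 2:nd) v[t] <- 0.6 * v[t - 1] + stats::rnorm(1, 0, 3)
    v
  })
  rasters <- vector("list", nd)
  for (t in seq_len(nd)) {
    st <- simulate_day_state(layout, t, ar[t], child_seed(config$seed, 100 + t))
    pw <- pw_for_rh(st$rh, st$ta, 40)
    sc <- generate_scene(layout, pw, st$ta, 40,
                         pw_variant = config$pw_variant,
                         seed = child_seed(config$seed, 5000 + t),
                         date = rh_dates[t])
    rh <- derive_rh(sc, variant = config$pw_variant, clamp = config$clamp)
    rasters[[t]] <- resample_nearest(rh, config$target_pixel_m)
  }

  ## stage 2: zonal extraction
  say("extract: area-weighted block means for %d blocks", length(layout$blocks))
  series <- build_block_series(rasters, layout)

  ## stage 3: synthetic census
  census <- generate_census(layout, stats::setNames(series, c("block_id", "date", "rh")),
                            spec = config$response,
                            cycles_per_year = config$cycles_per_year,
                            years = config$years, epoch = config$epoch,
                            window_days = config$window_days)
  write_census_csv(census, file.path(config$out_dir, "census.csv"))

  ## stage 4: lagged dataset + cleaning
  ds <- assemble_lagged(series, census, window_days = config$window_days)
  ds <- clean_dataset(ds, config$cleaning_rule)
  write_lagged_csv(ds, file.path(config$out_dir, "lagged_dataset.csv"))
  say("dataset: %d rows retained, %d dropped", nrow(ds),
      nrow(attr(ds, "cleaning_log")))

  ## stage 5: split and fit the nine configurations
  splits <- split_dataset(ds, seed = child_seed(config$seed, 2))
  models <- list()
  comparison <- list()
  ann_rows <- list()
  for (nm in names(config$model_configs)) {
    cc <- config$model_configs[[nm]]
    say("fit: configuration %s", nm)
    if (identical(cc, "auto")) {
      lin <- stepwise_select(splits$train, degree = 1L)
      pol <- stepwise_select(splits$train, degree = 2L)
      sel <- forward_select_features(ds, 1:6, config = config$train,
                                     hidden = max(config$hidden_range) %/% 2 + 1L,
                                     train = splits$train,
                                     validation = splits$validation)
      feats <- lag_names(sel$mask)
    } else {
      lin <- fit_regression(splits$train, lags = cc, degree = 1L)
      pol <- fit_regression(splits$train, lags = cc, degree = 2L)
      feats <- lag_names(cc)
    }
    arch <- search_architecture(ds, feats, hidden_range = config$hidden_range,
                                config = config$train,
                                train = splits$train,
                                validation = splits$validation)
    ann <- arch$best_model
    models[[nm]] <- list(linear = lin, polynomial = pol, ann = ann)
    ev <- function(m) evaluate_model(m, splits)
    ev_lin <- ev(lin); ev_pol <- ev(pol); ev_ann <- ev(ann)
    test_adj <- function(e) e$adjusted_r2[e$split == "test"]
    comparison[[nm]] <- data.frame(
      configuration = nm,
      linear = test_adj(ev_lin), polynomial = test_adj(ev_pol),
      ann = test_adj(ev_ann))
    get <- function(e, col, s) e[[col]][e$split == s]
    ann_rows[[nm]] <- data.frame(
      configuration = nm,
      architecture = sprintf("[%d-%d-1]", ann$architecture[1],
                             ann$architecture[2]),
      train_abs_error = get(ev_ann, "absolute_error", "train"),
      validation_abs_error = get(ev_ann, "absolute_error", "validation"),
      test_abs_error = get(ev_ann, "absolute_error", "test"),
      train_accuracy = get(ev_ann, "minmax_accuracy_percent", "train"),
      validation_accuracy = get(ev_ann, "minmax_accuracy_percent", "validation"),
      test_accuracy = get(ev_ann, "minmax_accuracy_percent", "test"))
    write_model_json(lin, file.path(config$out_dir,
                                    sprintf("model_%s_linear.json", gsub("[^A-Za-z0-9]", "", nm))))
    write_model_json(pol, file.path(config$out_dir,
                                    sprintf("model_%s_polynomial.json", gsub("[^A-Za-z0-9]", "", nm))))
    write_mlp_json(ann, file.path(config$out_dir,
                                  sprintf("model_%s_ann.json", gsub("[^A-Za-z0-9]", "", nm))))
  }
  comparison <- do.call(rbind, comparison)
  ann_report <- do.call(rbind, ann_rows)
  rownames(comparison) <- rownames(ann_report) <- NULL
  utils::write.csv(comparison,
                   file.path(config$out_dir, "comparison_adjusted_r2.csv"),
                   row.names = FALSE)
  utils::write.csv(ann_report, file.path(config$out_dir, "ann_report.csv"),
                   row.names = FALSE)

  ## stage 6: manifest
  manifest <- list(
    seed = config$seed,
    epoch = format(config$epoch),
    years = config$years, cycles_per_year = config$cycles_per_year,
    pw_variant = config$pw_variant, clamp = config$clamp,
    target_pixel_m = config$target_pixel_m,
    window_days = config$window_days,
    cleaning_rule = config$cleaning_rule,
    response = config$response[c("lag_weights", "response_shape",
                                 "response_params", "noise_sd",
                                 "count_floor", "count_cap", "seed")],
    train = unclass(config$train),
    hidden_range = config$hidden_range,
    n_rasters = nd,
    n_rows = nrow(ds),
    n_dropped = nrow(attr(ds, "cleaning_log")),
    package_version = as.character(utils::packageVersion("bagwormRH")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(series = series, census = census, dataset = ds,
                 splits = splits, models = models, comparison = comparison,
                 ann_report = ann_report, out_dir = config$out_dir))
}
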