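term_label <- function(lag, power) {
  if (power == 1) paste0("T", lag) else sprintf("T%d^%d", lag, power)
}

#' Construct a regression model from known coefficients
#'
#' Builds an `rh_reg` object directly from an intercept and per-term
#' coefficients, e.g. to evaluate a published model such as
#' `count = 15.81 - 0.23 * T1`. Terms are `(lag, power)` pairs labelled
#' `"T1"`, `"T1^2"`, ...
#'
#' @param intercept model intercept.
#' @param coefficients named numeric; names are term labels like `"T1"` or
#'   `"T3^2"`.
#' @param degree polynomial degree (1 or 2); inferred from the terms if `NULL`.
#' @param n,adj_r2 optional fit statistics to carry along.
#' @return An object of class `rh_reg`.
#' @examples
#' m <- regression_model(15.81, c(T1 = -0.23))
#' predict(m, c(T1 = 0))   # 15.81
#' @export
regression_model <- function(intercept, coefficients = numeric(0),
                             degree = NULL, n = NA_integer_, adj_r2 = NA_real_) {
  labs <- names(coefficients)
  parse_term <- function(lab) {
    m <- regmatches(lab, regexec("^T([1-6])(\\^([0-9]+))?$", lab))[[1]]
    if (length(m) == 0) stop(sprintf("bad term label '%s'", lab))
    c(lag = as.integer(m[2]),
      power = if (m[4] == "") 1L else as.integer(m[4]))
  }
  terms <- lapply(labs, parse_term)
  powers <- vapply(terms, `[[`, 0L, "power")
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 terms = terms,
                 degree = degree %||% if (length(powers) && max(powers) > 1) 2L else 1L,
                 fit_stats = list(n = n, adj_r2 = adj_r2),
                 fit = NULL, trace = NULL),
            class = "rh_reg")
}

#' Fit a linear or polynomial regression of counts on lagged RH
#'
#' Ordinary least squares of `mean_count_per_palm` on the selected lag
#' columns; with `degree = 2`, each selected lag enters at powers 1 and 2.
#' Refuses rank-deficient designs, naming the collinear terms.
#'
#' @param ds a `lagged_dataset` (or any data.frame with `mean_count_per_palm`
#'   and `rh_T1`..`rh_T6` columns).
#' @param lags integer vector of lags (1..6) to include.
#' @param degree 1 (linear) or 2 (adds squared terms).
#' @return An `rh_reg` with coefficients, term list, and fit statistics
#'   (`n`, adjusted R-squared); the underlying `lm` fit is kept in `$fit`.
#' @export
fit_regression <- function(ds, lags = 1:6, degree = 1L) {
  stopifnot(all(lags %in% 1:6), degree %in% 1:2)
  terms <- list()
  for (l in as.integer(sort(unique(lags)))) {
    terms <- c(terms, list(c(lag = l, power = 1L)))
    if (degree == 2L) terms <- c(terms, list(c(lag = l, power = 2L)))
  }
  fit_terms(ds, terms, degree)
}

# Fit OLS on an explicit term list; shared by fit_regression and stepwise.
fit_terms <- function(ds, terms, degree = NULL) {
  df <- as.data.frame(ds)
  y <- df$mean_count_per_palm
  n <- length(y)
  if (length(terms)) {
    X <- vapply(terms, function(tm) df[[lag_names(tm["lag"])]]^tm["power"],
                numeric(n))
    X <- matrix(X, nrow = n)
    colnames(X) <- vapply(terms, function(tm) term_label(tm["lag"], tm["power"]), "")
  } else {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  if (n <= ncol(X) + 1L) stop("not enough rows for the requested terms")
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- if (ncol(X)) stats::lm(y ~ ., data = dat)
         else stats::lm(y ~ 1, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(gsub("`", "", bad), collapse = ", ")))
  }
  coefs <- cf[-1]
  names(coefs) <- colnames(X)
  powers <- vapply(terms, `[[`, 0L, "power")
  structure(list(intercept = unname(cf[1]),
                 coefficients = coefs,
                 terms = terms,
                 degree = degree %||% if (length(powers) && max(powers) > 1) 2L else 1L,
                 fit_stats = list(n = n,
                                  adj_r2 = if (stats::var(y) == 0) 0
                                           else summary(fit)$adj.r.squared),
                 fit = fit, trace = NULL),
            class = "rh_reg")
}

#' @export
print.rh_reg <- function(x, digits = 4, ...) {
  rhs <- if (length(x$coefficients)) {
    paste(sprintf("%+.*g(%s)", digits, x$coefficients, names(x$coefficients)),
          collapse = " ")
  } else ""
  cat(sprintf("<rh_reg> count = %.*g %s\n", digits, x$intercept, rhs))
  if (!is.na(x$fit_stats$adj_r2))
    cat(sprintf("  n = %s, adjusted R^2 = %.4f\n", x$fit_stats$n, x$fit_stats$adj_r2))
  invisible(x)
}

#' @export
coef.rh_reg <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.rh_reg <- function(object, ...) {
  if (!is.null(object$fit)) summary(object$fit) else print(object)
}

#' @export
residuals.rh_reg <- function(object, ...) {
  if (is.null(object$fit)) stop("model was not fitted to data")
  stats::residuals(object$fit)
}

#' Predict counts from a regression model
#'
#' Exact arithmetic on the stored coefficients:
#' `intercept + sum_k beta_k * T_lag^power`. Predictions are not clamped, so
#' negative counts are possible, as with the published model equations.
#'
#' @param object an `rh_reg`.
#' @param newdata either a named numeric vector mapping lags to RH values
#'   (`c(T1 = 60, ...)`) or a data.frame with `rh_T1`..`rh_T6` columns.
#' @param ... unused.
#' @return Numeric prediction(s).
#' @export
predict.rh_reg <- function(object, newdata, ...) {
  get_lag <- function(lag) {
    if (is.data.frame(newdata)) {
      col <- lag_names(lag)
      if (!col %in% names(newdata)) stop(sprintf("missing column %s", col))
      newdata[[col]]
    } else {
      nm <- paste0("T", lag)
      if (!nm %in% names(newdata)) stop(sprintf("missing lag value %s", nm))
      unname(newdata[[nm]])
    }
  }
  out <- object$intercept
  for (i in seq_along(object$terms)) {
    tm <- object$terms[[i]]
    out <- out + object$coefficients[[i]] * get_lag(tm["lag"])^tm["power"]
  }
  if (is.data.frame(newdata)) as.numeric(out) else unname(out)
}

#' Pearson correlation screening by census cycle
#'
#' For every census cycle and lag, the Pearson correlation (across blocks)
#' between the count and the lagged RH, with a two-sided p-value and the
#' conventional significance stars (`*` 0.05, `**` 0.01, `***` 0.001,
#' `****` 0.0001). Cycle-lag cells with fewer than `min_n` complete pairs or
#' zero variance are omitted and logged.
#'
#' @param ds a `lagged_dataset`.
#' @param min_n minimum complete pairs per cell (default 3).
#' @return data.frame of class `correlation_table` with columns `cycle`,
#'   `lag`, `r`, `p_value`, `n`, `stars`; attribute `omitted` logs skipped
#'   cells.
#' @export
pearson_by_cycle <- function(ds, min_n = 3L) {
  df <- as.data.frame(ds)
  res <- list(); omitted <- list()
  for (cyc in sort(unique(df$cycle_index))) {
    sub <- df[df$cycle_index == cyc, ]
    for (k in 1:6) {
      x <- sub[[lag_names(k)]]
      y <- sub$mean_count_per_palm
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < min_n) {
        omitted[[length(omitted) + 1L]] <-
          data.frame(cycle = cyc, lag = k, reason = "too few pairs")
        next
      }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        omitted[[length(omitted) + 1L]] <-
          data.frame(cycle = cyc, lag = k, reason = "zero variance")
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      p <- ct$p.value
      stars <- if (p <= 1e-4) "****" else if (p <= 1e-3) "***"
               else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
      res[[length(res) + 1L]] <- data.frame(
        cycle = cyc, lag = k, r = unname(ct$estimate), p_value = p,
        n = sum(ok), stars = stars)
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(cycle = integer(0), lag = integer(0), r = numeric(0),
                         p_value = numeric(0), n = integer(0), stars = character(0))
  rownames(out) <- NULL
  structure(out,
            omitted = if (length(omitted)) do.call(rbind, omitted) else NULL,
            class = c("correlation_table", "data.frame"))
}

#' Stepwise term selection by partial F tests
#'
#' Classical forward-backward stepwise selection on the candidate terms (the
#' six lags, plus their squares when `degree = 2`): at each forward step the
#' candidate with the smallest partial p-value enters if it is below
#' `entry_p`; after every entry, terms whose p-value rose above `stay_p` are
#' removed, worst first. Ties are broken by smaller lag index, then lower
#' power. May return an intercept-only model.
#'
#' @param ds a `lagged_dataset`.
#' @param degree 1 or 2.
#' @param entry_p,stay_p entry / stay significance thresholds (default 0.15,
#'   a common statistical-package default).
#' @return An `rh_reg`; the selection trace (one row per step) is in
#'   `$trace`.
#' @export
stepwise_select <- function(ds, degree = 1L, entry_p = 0.15, stay_p = 0.15) {
  stopifnot(degree %in% 1:2)
  candidates <- list()
  for (l in 1:6) {
    candidates <- c(candidates, list(c(lag = l, power = 1L)))
    if (degree == 2L) candidates <- c(candidates, list(c(lag = l, power = 2L)))
  }
  lab <- function(tm) term_label(tm["lag"], tm["power"])
  cand_labs <- vapply(candidates, lab, "")
  in_model <- rep(FALSE, length(candidates))
  trace <- list()
  # p-value of each term in the model defined by `sel` (logical index)
  term_p <- function(sel) {
    fit <- tryCatch(fit_terms(ds, candidates[sel], degree), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    sm <- summary(fit$fit)$coefficients
    p <- rep(NA_real_, sum(sel))
    rn <- gsub("`", "", rownames(sm))
    idx <- match(vapply(candidates[sel], lab, ""), rn)
    p[!is.na(idx)] <- sm[idx[!is.na(idx)], 4]
    p
  }
  repeat {
    changed <- FALSE
    # forward
    best_p <- Inf; best_i <- NA_integer_
    order_i <- order(vapply(candidates, `[[`, 0L, "lag"),
                     vapply(candidates, `[[`, 0L, "power"))
    for (i in order_i) {
      if (in_model[i]) next
      sel <- in_model; sel[i] <- TRUE
      p <- term_p(sel)
      if (is.null(p)) next   # collinear / singular addition
      pi <- p[sum(sel[seq_len(i)])]
      if (is.na(pi)) next
      if (pi < best_p - 1e-12) { best_p <- pi; best_i <- i }
    }
    if (!is.na(best_i) && best_p <= entry_p) {
      in_model[best_i] <- TRUE
      changed <- TRUE
      trace[[length(trace) + 1L]] <-
        data.frame(step = "add", term = cand_labs[best_i], p = best_p)
      # backward sweep
      repeat {
        p <- term_p(in_model)
        if (is.null(p) || !length(p)) break
        worst <- which.max(ifelse(is.na(p), 1, p))
        if (max(p, na.rm = TRUE) > stay_p) {
          idx <- which(in_model)[worst]
          in_model[idx] <- FALSE
          trace[[length(trace) + 1L]] <-
            data.frame(step = "drop", term = cand_labs[idx], p = p[worst])
        } else break
      }
    }
    if (!changed) break
  }
  fit <- fit_terms(ds, candidates[in_model], degree)
  fit$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = character(0), term = character(0), p = numeric(0))
  fit
}

#' Serialize a regression model to JSON
#'
#' @param model an `rh_reg`.
#' @param path file path (`NULL` returns the JSON string).
#' @return `path` invisibly, or the JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- list(type = "regression",
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              degree = model$degree,
              fit_stats = model$fit_stats,
              trace = model$trace)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
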