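#' Quickprop training configuration
#'
#' Hyperparameters for [qp_mlp()]: full-batch quickprop with a growth-factor
#' cap `mu`, a plain gradient-descent fallback step of size `learning_rate`,
#' optional weight decay, and early stopping on validation error with the
#' given `patience`.
#'
#' @param max_epochs maximum training epochs (default 500).
#' @param learning_rate gradient-descent fallback step size (default 0.1).
#' @param mu quickprop maximum growth factor (> 1, default 1.75).
#' @param weight_decay L2 penalty coefficient added to the gradient (default 0).
#' @param patience epochs without validation improvement before stopping
#'   (default 25).
#' @param seed RNG seed for weight initialization.
#' @return A list of class `qp_config`.
#' @export
train_config <- function(max_epochs = 500L, learning_rate = 0.1, mu = 1.75,
                         weight_decay = 0, patience = 25L, seed = 1L) {
  stopifnot(mu > 1, patience >= 1, max_epochs >= 1, learning_rate > 0,
            weight_decay >= 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, mu = mu,
                 weight_decay = weight_decay,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "qp_config")
}

#' Scale columns to \[-1, 1\]
#'
#' Min-max scaling `x' = 2 (x - min) / (max - min) - 1` applied to the feature
#' and target columns; the per-column minima and maxima are returned so the
#' transform is exactly invertible. Constant columns map to 0 with a warning.
#'
#' @param table data.frame.
#' @param feature_cols,target_col column names to scale.
#' @return list with `scaled` (the data.frame with scaled columns) and
#'   `scaling` (named list of `c(min, max)` per column).
#' @export
scale_columns <- function(table, feature_cols, target_col) {
  cols <- c(feature_cols, target_col)
  scaling <- list()
  out <- table
  for (cc in cols) {
    v <- table[[cc]]
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    if (hi > lo) {
      out[[cc]] <- 2 * (v - lo) / (hi - lo) - 1
    } else {
      warning(sprintf("column '%s' is constant; scaled to 0", cc))
      out[[cc]] <- rep(0, length(v))
    }
    scaling[[cc]] <- c(min = lo, max = hi)
  }
  list(scaled = out, scaling = scaling)
}

scale_value <- function(v, s) {
  if (s["max"] > s["min"]) 2 * (v - s["min"]) / (s["max"] - s["min"]) - 1 else rep(0, length(v))
}

unscale_value <- function(v, s) {
  if (s["max"] > s["min"]) (v + 1) / 2 * (s["max"] - s["min"]) + s["min"] else rep(unname(s["min"]), length(v))
}

#' Split a dataset into training, testing and validation parts
#'
#' Seeded random partition with the floor rounding rule: the test and
#' validation parts get `floor(fraction * n)` rows each and training receives
#' the remainder (so 282 rows split 60/20/20 gives 170/56/56).
#'
#' @param ds data.frame.
#' @param fractions length-3 numeric (train, test, validation) summing to 1.
#' @param seed RNG seed for the shuffle.
#' @return list with elements `train`, `test`, `validation` (disjoint,
#'   exhaustive data.frames).
#' @export
split_dataset <- function(ds, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  n <- nrow(ds)
  if (n < 5L) stop("need at least 5 rows to split")
  n_test <- floor(fractions[2] * n)
  n_val <- floor(fractions[3] * n)
  idx <- with_seed(seed, sample.int(n))
  test_i <- idx[seq_len(n_test)]
  val_i <- idx[n_test + seq_len(n_val)]
  train_i <- idx[-seq_len(n_test + n_val)]
  list(train = ds[sort(train_i), , drop = FALSE],
       test = ds[sort(test_i), , drop = FALSE],
       validation = ds[sort(val_i), , drop = FALSE])
}

## ---- network internals -------------------------------------------------

logistic <- function(x) 1 / (1 + exp(-x))

# Forward pass in scaled space. X: n x k matrix. Returns list(H, O).
qp_forward <- function(w, X) {
  H <- logistic(sweep(X %*% w$W1, 2, w$b1, `+`))
  O <- logistic(sweep(H %*% w$W2, 2, w$b2, `+`))
  list(H = H, O = O)
}

# Gradient of E = 0.5 * mean((O - Y)^2) w.r.t. all weights.
qp_gradient <- function(w, X, Y) {
  fw <- qp_forward(w, X)
  n <- nrow(X)
  dO <- (fw$O - Y) * fw$O * (1 - fw$O) / n
  dH <- (dO %*% t(w$W2)) * fw$H * (1 - fw$H)
  list(W1 = t(X) %*% dH, b1 = colSums(dH),
       W2 = t(fw$H) %*% dO, b2 = sum(dO))
}

qp_error <- function(w, X, Y) {
  O <- qp_forward(w, X)$O
  0.5 * mean((O - Y)^2)
}

# One quickprop update for one weight array. prev holds step/grad from the
# previous epoch. The classical rule: the secant (quadratic) step
# S/(S_prev - S) * step_prev, magnitude capped at mu*|step_prev|; a plain
# gradient-descent step -lr*S whenever there is no usable previous step
# (first epoch, a vanished step -- the classical stagnation mode -- or a
# degenerate secant denominator) so training can always restart from the
# gradient.
# Fahlman's full per-weight rule, in gradient convention S = dE/dw (the
# descent direction is -S). With a usable previous step: take the secant
# (quadratic) step S/(S_prev - S) * step_prev, replaced by the maximum-growth
# step mu * step_prev when the slope has shrunk past the shrink factor
# mu/(1+mu) (which is where the secant step would exceed it or point
# backwards), and add a plain gradient term -lr*S while the slope still
# points along the previous step's direction. With no usable previous step
# (first epoch or a vanished step): plain gradient descent -lr*S.
qp_step <- function(S, S_prev, step_prev, lr, mu) {
  shrink <- mu / (1 + mu)
  slope <- -S
  slope_prev <- -S_prev
  usable_pos <- step_prev > 1e-10
  usable_neg <- step_prev < -1e-10
  quad <- step_prev * slope / (slope_prev - slope)
  growth <- mu * step_prev
  step <- ifelse(
    usable_pos,
    ifelse(slope > 0, lr * slope, 0) +
      ifelse(slope > shrink * slope_prev, growth, quad),
    ifelse(
      usable_neg,
      ifelse(slope < 0, lr * slope, 0) +
        ifelse(slope < shrink * slope_prev, growth, quad),
      lr * slope))
  ifelse(is.finite(step), step, lr * slope)
}

# Core batch quickprop loop on scaled matrices. Returns best-validation
# weights, error history, and the epoch of the best weights.
qp_train_core <- function(w, X, Y, Xv = NULL, Yv = NULL, cfg) {
  arrays <- c("W1", "b1", "W2", "b2")
  prev_step <- lapply(w[arrays], function(a) a * 0)
  prev_grad <- lapply(w[arrays], function(a) a * 0)
  best <- w; best_err <- Inf; best_epoch <- 0L
  hist <- matrix(NA_real_, cfg$max_epochs, 2L,
                 dimnames = list(NULL, c("train_mse", "val_mse")))
  wait <- 0L
  monitor_val <- !is.null(Xv) && nrow(Xv) > 0L
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    g <- qp_gradient(w, X, Y)
    if (cfg$weight_decay > 0)
      for (a in c("W1", "W2")) g[[a]] <- g[[a]] + cfg$weight_decay * w[[a]]
    for (a in arrays) {
      st <- qp_step(g[[a]], prev_grad[[a]], prev_step[[a]],
                    cfg$learning_rate, cfg$mu)
      w[[a]] <- w[[a]] + st
      prev_step[[a]] <- st
      prev_grad[[a]] <- g[[a]]
    }
    tr_err <- qp_error(w, X, Y)
    if (!is.finite(tr_err) || tr_err > 1e6)
      stop(sprintf("quickprop diverged at epoch %d (error %g)", epoch, tr_err))
    mon <- if (monitor_val) qp_error(w, Xv, Yv) else tr_err
    hist[epoch, ] <- c(2 * tr_err, if (monitor_val) 2 * mon else NA_real_)
    if (mon < best_err - 1e-12) {
      best_err <- mon; best <- w; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  list(weights = best, history = as.data.frame(hist[seq_len(epoch), , drop = FALSE]),
       best_epoch = best_epoch)
}

# Scaled target -> logistic space [0.1, 0.9]: keeps targets away from the
# logistic output's asymptotes. Inverse clamps to the training target range.
to_logistic_space <- function(t_scaled) (0.8 * t_scaled + 1) / 2
from_logistic_space <- function(o) pmin(pmax((2 * o - 1) / 0.8, -1), 1)

#' Fit a quickprop-trained multilayer perceptron
#'
#' Single-hidden-layer perceptron `k-h-1` with logistic activations on the
#' hidden and output layers, trained by full-batch quickprop. Features and
#' target are min-max scaled to \[-1, 1\]; internally the scaled target is
#' mapped into \[0.1, 0.9\] of the logistic output range to avoid asymptotic
#' saturation, and predictions are back-transformed (and thereby bounded by
#' the training target range). Training stops at `max_epochs` or when the
#' validation error (training error if no validation set is given) has not
#' improved for `patience` epochs; the weights with minimum monitored error
#' are returned.
#'
#' @param train data.frame of training rows.
#' @param features character vector of feature column names (e.g.
#'   `c("rh_T1", "rh_T2")`).
#' @param target target column name (default `"mean_count_per_palm"`).
#' @param hidden number of hidden units.
#' @param validation optional data.frame monitored for early stopping.
#' @param config a [train_config()].
#' @return An object of class `qp_mlp`: architecture, weights, scaling
#'   parameters, error history (`$history`, original-scale MSE per epoch),
#'   fitted values, and the fitness value `1 / (1 + validation mean absolute
#'   error)` used by the architecture and feature searches.
#' @examples
#' d <- data.frame(rh_T1 = runif(40, 47, 71))
#' d$mean_count_per_palm <- 20 - 0.2 * d$rh_T1 + rnorm(40, 0, 0.2)
#' fit <- qp_mlp(d, "rh_T1", hidden = 3, config = train_config(seed = 7))
#' print(fit)
#' @export
qp_mlp <- function(train, features, target = "mean_count_per_palm",
                   hidden = 5L, validation = NULL, config = train_config()) {
  stopifnot(length(features) >= 1L, hidden >= 1L)
  missing_cols <- setdiff(c(features, target), names(train))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  sc <- scale_columns(train, features, target)
  X <- as.matrix(sc$scaled[, features, drop = FALSE])
  Y <- matrix(to_logistic_space(sc$scaled[[target]]), ncol = 1)
  Xv <- NULL; Yv <- NULL
  if (!is.null(validation) && nrow(validation) > 0L) {
    Xv <- vapply(features, function(f)
      scale_value(validation[[f]], sc$scaling[[f]]), numeric(nrow(validation)))
    Xv <- matrix(Xv, nrow = nrow(validation))
    Yv <- matrix(to_logistic_space(
      scale_value(validation[[target]], sc$scaling[[target]])), ncol = 1)
  }
  k <- length(features)
  w0 <- with_seed(config$seed, list(
    W1 = matrix(stats::runif(k * hidden, -0.5, 0.5), k, hidden),
    b1 = stats::runif(hidden, -0.5, 0.5),
    W2 = matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1),
    b2 = stats::runif(1, -0.5, 0.5)))
  fitres <- qp_train_core(w0, X, Y, Xv, Yv, config)
  obj <- structure(list(architecture = c(n_in = k, n_hidden = as.integer(hidden),
                                         n_out = 1L),
                        weights = fitres$weights,
                        features = features, target = target,
                        scaling = sc$scaling, config = config,
                        history = fitres$history,
                        best_epoch = fitres$best_epoch),
                   class = "qp_mlp")
  obj$fitted <- predict(obj, train)
  obj$y <- train[[target]]
  val_abs <- if (!is.null(validation) && nrow(validation) > 0L) {
    mean(abs(predict(obj, validation) - validation[[target]]))
  } else {
    mean(abs(obj$fitted - obj$y))
  }
  obj$fitness <- 1 / (1 + val_abs)
  obj
}

#' Predict counts from a fitted quickprop MLP
#'
#' Forward pass in scaled space, then back-transformation to the original
#' count scale; outputs are bounded by the training target range (a logistic
#' output cannot extrapolate beyond it).
#'
#' @param object a `qp_mlp`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return Numeric predictions on the original scale.
#' @export
predict.qp_mlp <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols))
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  X <- vapply(object$features, function(f)
    scale_value(newdata[[f]], object$scaling[[f]]), numeric(nrow(newdata)))
  X <- matrix(X, nrow = nrow(newdata))
  o <- qp_forward(object$weights, X)$O
  t_scaled <- from_logistic_space(as.vector(o))
  unscale_value(t_scaled, object$scaling[[object$target]])
}

#' @export
print.qp_mlp <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("<qp_mlp> %d-%d-%d, logistic activations, quickprop-trained\n",
              a[1], a[2], a[3]))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  epochs run: %d (best at %d), fitness = %.4f\n",
              nrow(x$history), x$best_epoch, x$fitness))
  invisible(x)
}

#' @export
summary.qp_mlp <- function(object, ...) {
  print(object)
  cat(sprintf("  training MSE at best weights: %.5g\n",
              mean((object$fitted - object$y)^2)))
  cat(sprintf("  training MAE at best weights: %.5g\n",
              mean(abs(object$fitted - object$y))))
  invisible(object)
}

#' @export
coef.qp_mlp <- function(object, ...) object$weights

#' @export
residuals.qp_mlp <- function(object, ...) object$y - object$fitted

#' @export
plot.qp_mlp <- function(x, ...) {
  h <- x$history
  graphics::plot(seq_len(nrow(h)), h$train_mse, type = "l",
                 xlab = "epoch", ylab = "MSE (scaled space)",
                 main = "quickprop training history", ...)
  if (any(is.finite(h$val_mse)))
    graphics::lines(seq_len(nrow(h)), h$val_mse, lty = 2)
  invisible(x)
}

#' Hidden-layer size search by network fitness
#'
#' Trains one network per candidate hidden size and returns the size with the
#' best fitness `1 / (1 + validation mean absolute error)`; ties go to the
#' smaller size. When called with a full dataset and no explicit
#' train/validation pair, the dataset is split 60/20/20 with the config seed.
#'
#' @param ds data.frame (used as the full dataset if `train` is `NULL`).
#' @param features feature column names.
#' @param hidden_range candidate hidden sizes (default 1:10).
#' @param config a [train_config()].
#' @param train,validation optional explicit split overriding `ds`.
#' @param target target column name.
#' @return list with `best_hidden`, `fitness_table` (data.frame of hidden
#'   size and fitness) and `best_model`.
#' @export
search_architecture <- function(ds, features, hidden_range = 1:10,
                                config = train_config(),
                                train = NULL, validation = NULL,
                                target = "mean_count_per_palm") {
  if (length(hidden_range) == 0L) stop("empty hidden_range")
  if (is.null(train)) {
    sp <- split_dataset(ds, seed = config$seed)
    train <- sp$train; validation <- sp$validation
  }
  fits <- lapply(hidden_range, function(h)
    qp_mlp(train, features, target, hidden = h, validation = validation,
           config = config))
  fitness <- vapply(fits, `[[`, 0, "fitness")
  best <- which(fitness >= max(fitness) - 1e-12)[1]  # ties -> smallest size
  list(best_hidden = hidden_range[best],
       fitness_table = data.frame(hidden = hidden_range, fitness = fitness),
       best_model = fits[[best]])
}

#' Forward stepwise feature selection by network fitness
#'
#' Greedy forward selection over candidate lags: at each round the lag whose
#' addition gives the highest fitness is added if it improves on the current
#' mask's fitness; selection stops when no addition improves. The first round
#' always selects the best single feature.
#'
#' @param ds data.frame (split 60/20/20 with the config seed if no explicit
#'   `train`/`validation` is given).
#' @param candidate_lags integer lags (1..6) to consider.
#' @param config a [train_config()].
#' @param hidden hidden-layer size used for every candidate network.
#' @param train,validation optional explicit split.
#' @param target target column name.
#' @return list with `mask` (selected lags, increasing), `trace` (data.frame
#'   of per-step candidate fitness) and `best_model`.
#' @export
forward_select_features <- function(ds, candidate_lags = 1:6,
                                    config = train_config(), hidden = 5L,
                                    train = NULL, validation = NULL,
                                    target = "mean_count_per_palm") {
  stopifnot(length(candidate_lags) >= 1L)
  if (is.null(train)) {
    sp <- split_dataset(ds, seed = config$seed)
    train <- sp$train; validation <- sp$validation
  }
  selected <- integer(0)
  best_fitness <- -Inf
  best_model <- NULL
  trace <- list()
  remaining <- sort(candidate_lags)
  repeat {
    round_best <- -Inf; round_lag <- NA_integer_; round_model <- NULL
    for (l in remaining) {
      feats <- lag_names(sort(c(selected, l)))
      fit <- qp_mlp(train, feats, target, hidden = hidden,
                    validation = validation, config = config)
      trace[[length(trace) + 1L]] <-
        data.frame(step = length(selected) + 1L, candidate = l,
                   fitness = fit$fitness)
      if (fit$fitness > round_best + 1e-12) {
        round_best <- fit$fitness; round_lag <- l; round_model <- fit
      }
    }
    if (is.na(round_lag)) break
    if (length(selected) == 0L || round_best > best_fitness + 1e-12) {
      selected <- sort(c(selected, round_lag))
      remaining <- setdiff(remaining, round_lag)
      best_fitness <- round_best
      best_model <- round_model
      if (length(remaining) == 0L) break
    } else break
  }
  list(mask = selected, trace = do.call(rbind, trace), best_model = best_model)
}

#' Serialize a fitted MLP to JSON
#'
#' Records architecture, weights, scaling parameters, training configuration
#' and fitness, sufficient to reconstruct predictions.
#'
#' @param net a `qp_mlp`.
#' @param path file path (`NULL` returns the JSON string).
#' @return `path` invisibly, or the JSON string.
#' @export
write_mlp_json <- function(net, path = NULL) {
  obj <- list(type = "qp_mlp",
              architecture = as.list(net$architecture),
              weights = lapply(net$weights, function(m) unclass(as.matrix(m))),
              features = net$features, target = net$target,
              scaling = net$scaling,
              config = unclass(net$config),
              fitness = net$fitness, best_epoch = net$best_epoch)
  if (is.null(path)) return(jsonlite::toJSON(obj, digits = NA))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
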