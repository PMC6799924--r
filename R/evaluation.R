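#' Mean absolute error
#'
#' Average absolute difference between predicted and actual values.
#'
#' @param actual,predicted numeric vectors of equal length (>= 1).
#' @return Non-negative scalar.
#' @export
absolute_error <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) == 0L) stop("empty vectors")
  mean(abs(predicted - actual))
}

#' Min-max accuracy
#'
#' Agreement metric in percent. In `"elementwise"` mode (the formula):
#' the mean over observations of `min(actual, predicted) / max(actual,
#' predicted)`, times 100; a row where both values are 0 contributes ratio 1
#' (perfect agreement) and a row where exactly one value is 0 is excluded
#' with a warning. In `"pooled"` mode (the prose description): the ratio of
#' the smaller to the larger of the two vector means, times 100. Both
#' operands must be non-negative; shift or clamp predictions first if they
#' are not.
#'
#' @param actual,predicted non-negative numeric vectors of equal length.
#' @param mode `"elementwise"` (default) or `"pooled"`.
#' @return Percentage in \[0, 100\], with attribute `mode`.
#' @examples
#' minmax_accuracy(c(2, 4), c(2, 4))   # 100
#' minmax_accuracy(c(2, 4), c(4, 8))   # 50
#' @export
minmax_accuracy <- function(actual, predicted,
                            mode = c("elementwise", "pooled")) {
  mode <- match.arg(mode)
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (any(actual < 0, na.rm = TRUE) || any(predicted < 0, na.rm = TRUE))
    stop("min-max accuracy requires non-negative values; shift or clamp first")
  val <- if (mode == "elementwise") {
    hi <- pmax(actual, predicted)
    lo <- pmin(actual, predicted)
    ratio <- ifelse(hi == 0, 1, lo / hi)
    one_zero <- hi > 0 & lo == 0
    if (any(one_zero, na.rm = TRUE)) {
      warning(sprintf("%d row(s) with exactly one zero excluded",
                      sum(one_zero, na.rm = TRUE)))
      ratio <- ratio[!one_zero]
    }
    100 * mean(ratio, na.rm = TRUE)
  } else {
    ma <- mean(actual, na.rm = TRUE); mp <- mean(predicted, na.rm = TRUE)
    if (max(ma, mp) == 0) 100 else 100 * min(ma, mp) / max(ma, mp)
  }
  structure(val, mode = mode)
}

#' Adjusted R-squared between actual and predicted values
#'
#' R-squared of the simple regression of actual on predicted, adjusted for
#' the number of model terms: `1 - (1 - R^2) (n - 1) / (n - p - 1)`. This is
#' the model-agnostic comparison statistic applied to both regression and
#' network predictions; for network outputs the default `p_terms = 1` (the
#' single regression slope) is used, for a fitted regression its number of
#' terms is the natural choice.
#'
#' @param actual,predicted numeric vectors, `length > p_terms + 1`.
#' @param p_terms number of model terms used in the penalty (default 1).
#' @return Scalar adjusted R-squared (can be negative; at most 1).
#' @export
adjusted_r2_actual_vs_predicted <- function(actual, predicted, p_terms = 1L) {
  n <- length(actual)
  if (n != length(predicted)) stop("length mismatch")
  if (n <= p_terms + 1L) stop("too few observations for the adjustment")
  if (stats::sd(predicted) == 0) stop("zero variance in predicted values")
  r2 <- stats::cor(actual, predicted)^2
  1 - (1 - r2) * (n - 1) / (n - p_terms - 1)
}

#' Evaluate a fitted model on data splits
#'
#' Applies the three comparison metrics (mean absolute error, min-max
#' accuracy, actual-vs-predicted adjusted R-squared) to each provided split.
#' Negative predictions (possible for unclamped regressions) are clamped to
#' zero for the min-max accuracy only, which requires non-negative operands.
#'
#' @param model an `rh_reg` or `qp_mlp` (anything with a `predict` method
#'   accepting the split data.frames).
#' @param splits named list of data.frames (e.g. `train`, `validation`,
#'   `test`), each with the model's feature columns and
#'   `mean_count_per_palm`.
#' @param p_terms penalty terms for the adjusted R-squared; default: number
#'   of model terms for `rh_reg`, 1 for anything else.
#' @param accuracy_mode passed to [minmax_accuracy()].
#' @return data.frame of class `eval_report`: one row per split with `n`,
#'   `absolute_error`, `minmax_accuracy_percent`, `adjusted_r2`; metadata in
#'   attributes.
#' @export
evaluate_model <- function(model, splits, p_terms = NULL,
                           accuracy_mode = "elementwise") {
  stopifnot(is.list(splits), length(splits) > 0L, !is.null(names(splits)))
  if (is.null(p_terms))
    p_terms <- if (inherits(model, "rh_reg")) max(1L, length(model$terms)) else 1L
  rows <- lapply(names(splits), function(nm) {
    d <- splits[[nm]]
    if (nrow(d) == 0L) stop(sprintf("empty split '%s'", nm))
    pred <- predict(model, d)
    act <- d$mean_count_per_palm
    adj <- tryCatch(adjusted_r2_actual_vs_predicted(act, pred, p_terms),
                    error = function(e) NA_real_)
    data.frame(split = nm, n = nrow(d),
               absolute_error = absolute_error(act, pred),
               minmax_accuracy_percent =
                 as.numeric(minmax_accuracy(act, pmax(pred, 0),
                                            mode = accuracy_mode)),
               adjusted_r2 = adj)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            model_class = class(model)[1],
            p_terms = p_terms,
            accuracy_mode = accuracy_mode,
            class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> (%s, p = %d, accuracy mode = %s)\n",
              attr(x, "model_class"), attr(x, "p_terms"),
              attr(x, "accuracy_mode")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
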