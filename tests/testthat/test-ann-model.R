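test_that("min-max scaling hits the endpoints and inverts exactly", {
  d <- data.frame(a = c(2, 5, 8), b = c(-1, 0, 3), y = c(10, 20, 30))
  sc <- scale_columns(d, c("a", "b"), "y")
  expect_equal(sc$scaled$a, c(-1, 0, 1))
  expect_equal(sc$scaled$y, c(-1, 0, 1))
  # midpoint maps to 0; round-trip is identity to 1e-12
  for (cc in c("a", "b", "y")) {
    back <- unscale_value(sc$scaled[[cc]], sc$scaling[[cc]])
    expect_equal(back, d[[cc]], tolerance = 1e-12)
  }
  # constant column maps to 0 with a warning
  d2 <- data.frame(a = c(1, 1, 1), y = 1:3)
  expect_warning(sc2 <- scale_columns(d2, "a", "y"), "constant")
  expect_true(all(sc2$scaled$a == 0))
})

test_that("the 60/20/20 split follows the floor rounding rule", {
  sizes <- function(n) {
    sp <- split_dataset(data.frame(x = seq_len(n)), seed = 1)
    c(nrow(sp$train), nrow(sp$test), nrow(sp$validation))
  }
  expect_equal(sizes(282), c(170, 56, 56))
  expect_equal(sizes(10), c(6, 2, 2))
  expect_equal(sizes(5), c(3, 1, 1))
  # disjoint and exhaustive
  sp <- split_dataset(data.frame(x = 1:100), seed = 3)
  all_x <- c(sp$train$x, sp$test$x, sp$validation$x)
  expect_equal(sort(all_x), 1:100)
  expect_error(split_dataset(data.frame(x = 1:4)), "at least 5")
})

test_that("zero network outputs 0.5 in scaled space for any input", {
  w <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 4),
            W2 = matrix(0, 4, 1), b2 = 0)
  X <- matrix(rnorm(15), 5, 3)
  expect_true(all(qp_forward(w, X)$O == 0.5))
})

test_that("first quickprop epoch equals the hand-derived gradient step", {
  # 1-1-1 network, one sample; symbolic backprop written out by hand
  w <- list(W1 = matrix(0.3, 1, 1), b1 = 0.1, W2 = matrix(-0.2, 1, 1), b2 = 0.05)
  x <- 0.7; y <- 0.9
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(w$W1[1] * x + w$b1)
  o <- sig(w$W2[1] * h + w$b2)
  d_o <- (o - y) * o * (1 - o)          # n = 1, so mean() is identity
  g_W2 <- d_o * h; g_b2 <- d_o
  d_h <- d_o * w$W2[1] * h * (1 - h)
  g_W1 <- d_h * x; g_b1 <- d_h
  lr <- 0.1
  cfg <- train_config(max_epochs = 1, learning_rate = lr, patience = 5)
  out <- qp_train_core(w, matrix(x, 1, 1), matrix(y, 1, 1), cfg = cfg)
  expect_equal(out$weights$W1[1], 0.3 - lr * g_W1, tolerance = 1e-12)
  expect_equal(out$weights$b1, 0.1 - lr * g_b1, tolerance = 1e-12)
  expect_equal(out$weights$W2[1], -0.2 - lr * g_W2, tolerance = 1e-12)
  expect_equal(out$weights$b2, 0.05 - lr * g_b2, tolerance = 1e-12)
})

test_that("quickprop step rule follows the classical per-weight cases", {
  # no previous step -> plain gradient descent
  S <- c(0.4, -0.2, 0)
  expect_equal(qp_step(S, S * 0, S * 0, lr = 0.1, mu = 1.75), -0.1 * S)
  # a vanished previous step also restarts from the gradient
  expect_equal(qp_step(0.4, 0.2, 1e-12, lr = 0.1, mu = 1.75), -0.1 * 0.4)
  # consistent descent (slope 0.1 after 0.3, step +0.05): secant step
  # 0.05*0.1/(0.3-0.1) plus the aligned gradient term 0.1*0.1
  st <- qp_step(S = -0.1, S_prev = -0.3, step_prev = 0.05, lr = 0.1, mu = 1.75)
  expect_equal(st, 0.05 * 0.1 / (0.3 - 0.1) + 0.1 * 0.1)
  # slope still steep (0.25 > shrink*0.3): maximum growth mu*step_prev
  # plus the gradient term
  st2 <- qp_step(S = -0.25, S_prev = -0.3, step_prev = 0.05, lr = 0.1, mu = 1.75)
  expect_equal(st2, 1.75 * 0.05 + 0.1 * 0.25)
  # slope flipped against the previous step with a degenerate secant
  # denominator: falls back to gradient descent
  st3 <- qp_step(S = 0.3, S_prev = 0.3, step_prev = 0.05, lr = 0.1, mu = 1.75)
  expect_equal(st3, -0.1 * 0.3)
  # overshoot (slope sign flipped): secant backtracks, no gradient term
  st4 <- qp_step(S = 0.1, S_prev = -0.3, step_prev = 0.05, lr = 0.1, mu = 1.75)
  expect_equal(st4, 0.05 * (-0.1) / (0.3 + 0.1))
})

test_that("the network fits noiseless linear and XOR-style targets", {
  # noiseless linear target: training MSE below 1e-3 within budget
  set.seed(21)
  d <- data.frame(rh_T1 = runif(60, 47, 71))
  d$mean_count_per_palm <- 28 - 0.35 * d$rh_T1
  fit <- qp_mlp(d, "rh_T1", hidden = 3,
                config = train_config(max_epochs = 2000, patience = 2000,
                                      seed = 5, learning_rate = 0.5))
  expect_lt(mean((predict(fit, d) - d$mean_count_per_palm)^2), 1e-3)

  # XOR pattern with 4 hidden units fitted below 0.05 MSE
  xor_d <- data.frame(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1),
                      y = c(0, 1, 1, 0))
  xfit <- qp_mlp(xor_d, c("x1", "x2"), target = "y", hidden = 4,
                 config = train_config(max_epochs = 5000, patience = 5000,
                                       seed = 1, learning_rate = 0.5))
  expect_lt(mean((predict(xfit, xor_d) - xor_d$y)^2), 0.05)
})

test_that("training is seed-deterministic and predictions are bounded", {
  d <- make_lagged_df(80, seed = 11,
                      signal = function(x) 30 - 0.4 * x$rh_T2, noise_sd = 1)
  cfg <- train_config(max_epochs = 150, seed = 17)
  f1 <- qp_mlp(d, c("rh_T1", "rh_T2"), hidden = 4, config = cfg)
  f2 <- qp_mlp(d, c("rh_T1", "rh_T2"), hidden = 4, config = cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
  # identical inputs -> identical outputs; outputs within training target range
  newd <- make_lagged_df(50, seed = 12, signal = function(x) 0)
  p1 <- predict(f1, newd)
  expect_identical(p1, predict(f1, newd))
  expect_true(all(p1 >= min(d$mean_count_per_palm) - 1e-9))
  expect_true(all(p1 <= max(d$mean_count_per_palm) + 1e-9))
  expect_error(predict(f1, newd[, "rh_T3", drop = FALSE]), "missing feature")
})

test_that("architecture search maximizes fitness with smallest-size tie-break", {
  d <- make_lagged_df(100, seed = 13,
                      signal = function(x) 25 - 0.3 * x$rh_T1, noise_sd = 0.5)
  cfg <- train_config(max_epochs = 100, seed = 3)
  # range of size one returns that size
  one <- search_architecture(d, "rh_T1", hidden_range = 4, config = cfg)
  expect_equal(one$best_hidden, 4)
  res <- search_architecture(d, "rh_T1", hidden_range = 1:4, config = cfg)
  expect_true(res$best_hidden %in% 1:4)
  expect_equal(nrow(res$fitness_table), 4L)
  expect_equal(res$best_hidden,
               res$fitness_table$hidden[
                 which(res$fitness_table$fitness >=
                         max(res$fitness_table$fitness) - 1e-12)[1]])
  expect_error(search_architecture(d, "rh_T1", hidden_range = integer(0),
                                   config = cfg), "empty")
})

test_that("forward feature selection recovers the informative lag", {
  d <- make_lagged_df(150, seed = 14,
                      signal = function(x) 30 - 0.5 * x$rh_T4, noise_sd = 0.5)
  cfg <- train_config(max_epochs = 120, seed = 2)
  sel <- forward_select_features(d, 1:6, config = cfg, hidden = 3)
  # the informative lag is in the mask and was chosen first
  expect_true(4L %in% sel$mask)
  first_round <- sel$trace[sel$trace$step == 1, ]
  expect_equal(first_round$candidate[which.max(first_round$fitness)], 4L)
  # exhaustive single-feature oracle agrees on the winner
  single_fit <- vapply(1:6, function(l) {
    sp <- split_dataset(d, seed = cfg$seed)
    qp_mlp(sp$train, paste0("rh_T", l), hidden = 3,
           validation = sp$validation, config = cfg)$fitness
  }, 0)
  expect_equal(which.max(single_fit), 4L)
})

test_that("fitted networks serialize to JSON with weights intact", {
  d <- make_lagged_df(40, seed = 15, signal = function(x) x$rh_T1 / 4)
  fit <- qp_mlp(d, "rh_T1", hidden = 2, config = train_config(max_epochs = 30))
  p <- tempfile(fileext = ".json")
  write_mlp_json(fit, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$architecture$n_hidden, 2L)
  expect_equal(matrix(back$weights$W1, 1, 2), unclass(fit$weights$W1),
               tolerance = 1e-12, ignore_attr = TRUE)
})
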