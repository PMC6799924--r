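# Small in-code fixtures shared across test files.

# Lagged-style data.frame with six RH lag columns and a count generated by
# `signal` (a function of the data.frame) plus Gaussian noise.
make_lagged_df <- function(n = 60, seed = 1, signal = function(d) 0,
                           noise_sd = 0, cycles = NULL) {
  set.seed(seed)
  d <- as.data.frame(matrix(runif(n * 6, 47, 71), n, 6))
  names(d) <- paste0("rh_T", 1:6)
  d$mean_count_per_palm <- signal(d) + rnorm(n, 0, noise_sd)
  d$cycle_index <- cycles %||% rep(seq_len(ceiling(n / 10)), each = 10)[seq_len(n)]
  d$block_id <- sprintf("B%02d", seq_len(n) %% 26 + 1)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform-value grid helper.
const_grid <- function(value, nr = 2, nc = 2, pixel = 1000, date = NULL) {
  rh_grid(matrix(value, nr, nc), xmin = 0, ymax = nr * pixel, pixel = pixel,
          date = date)
}

# Independent scalar implementation of the full retrieval chain, written
# straight from the printed formulas; used as the pixelwise oracle.
scalar_rh_oracle <- function(r865, r1240, r905, r936, r940, ta, h,
                             variant = "as_printed_grouped") {
  pwf <- function(tobs, a, b) {
    switch(variant,
           as_printed_grouped = ((a - tobs) / b)^2,
           as_printed_literal = (a - tobs / b)^2,
           log_form = ((a - log(tobs)) / b)^2)
  }
  t17 <- r905 / r865
  t18 <- r936 / r865
  t19 <- r940 / (0.8 * r865 + 0.2 * r1240)
  pw <- 0.36 * pwf(t17, 0.025, 0.30) + 0.24 * pwf(t18, 0.056, 0.60) +
    0.40 * pwf(t19, 0.120, 0.651)
  q <- 0.001 * (-0.0762 * pw^2 + 1.753 * pw + 12.405)
  pa <- 1013.3 - 0.1038 * h
  e <- q * pa / 0.622
  es <- 611 * exp(17.27 * ta / (237.3 + ta)) / 100
  min(max(100 * e / es, 0), 100)
}
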