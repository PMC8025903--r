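# brute-force two-way sum-of-squares oracle: explicit double loops, no shared
# code with the engine
ss_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  row_means <- numeric(n)
  for (i in seq_len(n)) row_means[i] <- sum(x[i, ]) / k
  col_means <- numeric(k)
  for (j in seq_len(k)) col_means[j] <- sum(x[, j]) / n
  ss_rows <- 0; ss_cols <- 0; ss_error <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (row_means[i] - grand)^2
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (col_means[j] - grand)^2
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_error <- ss_error +
        (x[i, j] - row_means[i] - col_means[j] + grand)^2
    }
  }
  list(ms_rows = unname(ss_rows / (n - 1)),
       ms_cols = unname(ss_cols / (k - 1)),
       ms_error = unname(ss_error / ((n - 1) * (k - 1))))
}

icc_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  ms <- ss_oracle(x)
  (ms$ms_rows - ms$ms_error) /
    (ms$ms_rows + (k - 1) * ms$ms_error + (k / n) * (ms$ms_cols - ms$ms_error))
}

# predicted absolute-agreement ICC for an attending/trainee pair under the
# clipped +/-1 per-factor disagreement model, from the exact per-case moments
# of the total shift: mu_i = (p/2)(n1_i - n5_i), v_i = p * n_mid_i +
# (p/2 - p^2/4)(n1_i + n5_i), plugged into the expected mean squares of the
# two-way decomposition with one noiseless rater
predict_icc_from_noise <- function(attending, ids, p) {
  fs <- as.matrix(attending[ids])
  n1 <- rowSums(fs == 1)
  n5 <- rowSums(fs == 5)
  nmid <- rowSums(fs >= 2 & fs <= 4)
  mu <- (p / 2) * (n1 - n5)
  v <- nmid * p + (n1 + n5) * (p / 2 - p^2 / 4)
  t <- attending$total
  n <- length(t)
  var_d <- mean(v) + stats::var(mu)
  mse <- var_d / 2
  msr <- 2 * (stats::var(t + mu / 2) + mean(v) / 4)
  msc <- n * mean(mu)^2 / 2 + var_d / 2
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

random_rating_matrix <- function(n, k) {
  matrix(round(stats::runif(n * k, 16, 80) + stats::rnorm(n * k)), n, k)
}
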