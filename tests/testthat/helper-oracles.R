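# Independent brute-force oracles, written from textbook formulas with
# explicit loops/sums; deliberately on a different code path from the
# package implementations they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; sx <- 0; sy <- 0
  for (k in seq_len(n)) {
    num <- num + (x[k] - mx) * (y[k] - my)
    sx <- sx + (x[k] - mx)^2
    sy <- sy + (y[k] - my)^2
  }
  if (sx == 0 || sy == 0) return(NA_real_)
  num / sqrt(sx * sy)
}

oracle_ndp <- function(x, y) {
  dot <- 0; nx <- 0; ny <- 0
  for (k in seq_along(x)) {
    dot <- dot + x[k] * y[k]
    nx <- nx + x[k]^2
    ny <- ny + y[k]^2
  }
  if (nx == 0 || ny == 0) return(NA_real_)
  dot / sqrt(nx * ny)
}

oracle_sf <- function(x, y) {
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0) return(NA_real_)
  if (nx < ny) nx / ny else ny / nx
}

# Pooled-variance two-sample t statistic and two-sided p, by the formula.
oracle_two_sample_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2,
       p = 2 * pt(-abs(t), nx + ny - 2))
}

# ANCOVA group F-test by explicit normal equations: residual sums of
# squares of y ~ 1 + x versus y ~ 1 + x + g, F = ((RSS0-RSS1)/1)/(RSS1/df).
oracle_ancova_p_group <- function(s_input, s_output, group) {
  g <- as.numeric(factor(group)) - 1
  fit_rss <- function(X, y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  X0 <- cbind(1, s_input)
  X1 <- cbind(1, s_input, g)
  rss0 <- fit_rss(X0, s_output)
  rss1 <- fit_rss(X1, s_output)
  df1 <- length(s_output) - ncol(X1)
  f <- (rss0 - rss1) / (rss1 / df1)
  1 - pf(f, 1, df1)
}

make_binned <- function(counts, bin_width = 0.01) {
  binned_train(counts, bin_width, bin_width * length(counts))
}

# Identity-responder recording: every output sweep repeats its input train.
identity_recording <- function(input_set, n_repetitions = 10) {
  simulate_granule_cell(input_set, p_spike = 1, latency_mean = 0,
                        latency_sd = 0, p_extra = 0, refractory = 0,
                        spontaneous_rate = 0,
                        n_repetitions = n_repetitions, seed = 1)
}
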