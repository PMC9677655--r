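test_that("metric values match hand-computed examples", {
  a <- make_binned(c(1, 0, 2, 1))
  b <- make_binned(c(0, 1, 1, 2))
  expect_equal(pearson_r(a, b), 0)            # centered vectors orthogonal
  expect_equal(ndp(a, b), 4 / 6)              # dot 4, both norms sqrt(6)
  expect_equal(scaling_factor(a, b), 1)       # equal norms

  expect_equal(ndp(make_binned(c(1, 0)), make_binned(c(0, 1))), 0)
  expect_equal(ndp(make_binned(c(1, 1)), make_binned(c(2, 2))), 1)
  expect_equal(scaling_factor(make_binned(c(2, 0)), make_binned(c(1, 0))),
               0.5)
})

test_that("undefined pairs return NA and mismatched binning errors", {
  zeros <- make_binned(c(0, 0, 0, 0))
  a <- make_binned(c(1, 0, 2, 1))
  const <- make_binned(c(1, 1, 1, 1))
  expect_true(is.na(pearson_r(zeros, a)))
  expect_true(is.na(pearson_r(const, a)))   # zero variance, nonzero norm
  expect_true(is.na(ndp(zeros, a)))
  expect_true(is.na(scaling_factor(zeros, a)))
  expect_false(is.na(ndp(const, a)))        # NDP only needs a nonzero norm

  b5 <- binned_train(c(1, 0, 1, 0, 1), 0.01, 0.05)
  expect_error(pearson_r(a, b5), "same bin")
  expect_error(ndp(a, binned_train(c(1, 0, 2, 1), 0.02, 0.08)), "same bin")
})

test_that("metrics are symmetric with unit self-similarity and obey the scale law", {
  set.seed(42)
  for (rep in 1:25) {
    x <- make_binned(rpois(30, 0.8))
    y <- make_binned(rpois(30, 0.8))
    for (f in list(pearson_r, ndp, scaling_factor))
      expect_equal(f(x, y), f(y, x))
    if (sum(x$counts) > 0 && var(as.numeric(x$counts)) > 0) {
      expect_equal(pearson_r(x, x), 1)
      expect_equal(ndp(x, x), 1)
      expect_equal(scaling_factor(x, x), 1)
      for (k in 2:4) {
        xk <- make_binned(k * x$counts)
        expect_equal(ndp(x, xk), 1)
        expect_equal(scaling_factor(x, xk), 1 / k)
      }
    }
  }
})

test_that("metrics agree with brute-force oracles on random small vectors", {
  set.seed(99)
  for (rep in 1:200) {
    len <- sample(2:20, 1)
    x <- sample(0:5, len, replace = TRUE)
    y <- sample(0:5, len, replace = TRUE)
    bx <- make_binned(x); by <- make_binned(y)
    expect_equal(pearson_r(bx, by), oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(ndp(bx, by), oracle_ndp(x, y), tolerance = 1e-12)
    expect_equal(scaling_factor(bx, by), oracle_sf(x, y), tolerance = 1e-12)
  }
})

test_that("pairwise input similarity covers all unordered pairs", {
  st <- spike_train(c(0.1, 0.55, 1.2), 2)
  same <- lapply(1:5, function(i) st)
  for (m in c("R", "NDP", "SF")) {
    ps <- pairwise_input_similarity(same, m)
    expect_equal(nrow(ps$pairs), 10)
    expect_equal(ps$pairs$value, rep(1, 10))
    expect_equal(ps$mean, 1)
  }
  # pairwise-orthogonal one-spike trains: NDP all zero
  ortho <- lapply(1:5, function(i)
    spike_train((i - 1) * 0.4 + 0.005, 2))
  ps <- pairwise_input_similarity(ortho, "NDP")
  expect_equal(ps$pairs$value, rep(0, 10))
  # generated set: mean R within the generator's calibration band
  iset <- generate_input_set(seed = 31)
  ps <- pairwise_input_similarity(iset, "R", 0.01)
  expect_equal(ps$mean, 0.76, tolerance = 0.02 / 0.76)
  expect_equal(ps$mean, iset$realized_r)
})

test_that("input/output similarity has protocol combinatorics and an exact identity diagonal", {
  iset <- generate_input_set(seed = 32)
  rec <- identity_recording(iset)
  expect_length(rec$outputs, 50)
  for (m in c("R", "NDP", "SF")) {
    io <- input_output_similarity(rec, m)
    expect_equal(nrow(io), 10)                      # one row per input pair
    expect_equal(io$n_output_pairs, rep(100L, 10))  # 10 x 10 cross sweeps
    expect_identical(io$s_output, io$s_input)       # exactly on the diagonal
    ss <- separation_summary(io)
    expect_equal(ss$fraction_below_diagonal, 0)
    expect_equal(ss$mean_s_output, ss$mean_s_input)
  }
})

test_that("identity diagonal is exact at other bin widths too", {
  iset <- generate_input_set(seed = 33)
  rec <- identity_recording(iset, n_repetitions = 3)
  for (w in c(0.005, 0.02, 0.05)) {
    io <- input_output_similarity(rec, "NDP", bin_width = w)
    expect_identical(io$s_output, io$s_input)
  }
})

test_that("input-ignoring Poisson outputs give near-zero output correlation", {
  iset <- generate_input_set(seed = 34)
  set.seed(55)
  # responder that ignores the stimulus entirely: background firing only
  s_out <- replicate(40, {
    rec <- simulate_granule_cell(iset, p_spike = 0, spontaneous_rate = 10,
                                 n_repetitions = 2,
                                 seed = sample.int(1e6, 1))
    mean(input_output_similarity(rec, "R")$s_output, na.rm = TRUE)
  })
  # Monte-Carlo band: mean pairwise R of independent trains is centered on 0
  expect_lt(abs(mean(s_out)), 0.02)
})

test_that("separation summary arithmetic and undefined handling", {
  pairs <- data.frame(s_input = c(0.8, 0.7), s_output = c(0.3, 0.9))
  ss <- separation_summary(pairs)
  expect_equal(ss$fraction_below_diagonal, 0.5)
  expect_equal(ss$mean_s_output, 0.6)

  pairs <- data.frame(s_input = c(0.5, 0.6), s_output = c(0, 0))
  expect_equal(separation_summary(pairs)$fraction_below_diagonal, 1)

  pairs$s_output <- NA_real_
  expect_error(separation_summary(pairs), "undefined")
})

test_that("output reliability uses same-input sweep pairs only", {
  iset <- generate_input_set(seed = 35)
  rec <- identity_recording(iset, n_repetitions = 4)
  rel <- output_reliability(rec, "R")
  expect_equal(nrow(rel), 5)
  expect_equal(rel$n_pairs, rep(6L, 5))      # choose(4, 2) per input
  expect_equal(rel$mean_similarity, rep(1, 5))
})
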