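test_that("t-tests match the textbook formulas and degenerate conventions", {
  set.seed(5)
  for (rep in 1:25) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    res <- two_sample_t(x, y)
    ora <- oracle_two_sample_t(x, y)
    expect_equal(res$statistic, ora$t, tolerance = 1e-8)
    expect_equal(res$df, ora$df)
    expect_equal(res$p_value, ora$p, tolerance = 1e-8)
  }
  x <- rnorm(10)
  same <- two_sample_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_message(res <- two_sample_t(rep(1, 5), rep(1, 6)), "zero variance")
  expect_equal(res$p_value, 1)

  expect_message(res1 <- one_sample_t(rep(0.5, 8), 0.5), "zero variance")
  expect_equal(res1$p_value, 1)
  expect_error(two_sample_t(1, c(1, 2)), "two observations")
})

test_that("one-sample t-test has power against a shifted discrimination index", {
  set.seed(6)
  rej <- replicate(500, {
    di <- rnorm(12, 0.66, 0.1)
    one_sample_t(di, 0.5)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.95)
})

test_that("ANCOVA recovers exact lines and agrees with the normal-equations oracle", {
  # both groups exactly on one line, zero noise
  d <- data.frame(s_input = rep(seq(0.2, 0.9, length.out = 10), 2),
                  s_output = NA,
                  group = rep(c("SH", "EE"), each = 10))
  d$s_output <- 0.1 + 0.5 * d$s_input
  anc <- ancova_compare(d)
  expect_equal(anc$coefficients$slope, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(anc$coefficients$intercept, c(0.1, 0.1), tolerance = 1e-10)

  set.seed(7)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    d <- data.frame(s_input = runif(2 * n, 0.2, 0.9),
                    group = rep(c("SH", "EE"), each = n))
    d$s_output <- 0.1 + 0.5 * d$s_input +
      ifelse(d$group == "EE", runif(1, -0.1, 0.1), 0) + rnorm(2 * n, 0, 0.05)
    anc <- ancova_compare(d)
    expect_equal(anc$p_group,
                 oracle_ancova_p_group(d$s_input, d$s_output, d$group),
                 tolerance = 1e-8)
  }
})

test_that("ANCOVA rejects degenerate designs", {
  d <- data.frame(s_input = runif(10), s_output = runif(10), group = "SH")
  expect_error(ancova_compare(d), "two groups")
  d$group <- rep(c("SH", "EE"), 5)
  d$s_input <- 0.5
  expect_error(ancova_compare(d), "constant")
})

test_that("group-line fits pass through the group means", {
  set.seed(8)
  d <- data.frame(s_input = runif(60, 0.2, 0.9),
                  group = rep(c("SH", "EE"), each = 30))
  d$s_output <- 0.2 + 0.4 * d$s_input + rnorm(60, 0, 0.05)
  anc <- ancova_compare(d)
  for (g in c("SH", "EE")) {
    co <- anc$coefficients[anc$coefficients$group == g, ]
    dg <- d[d$group == g, ]
    expect_equal(co$intercept + co$slope * mean(dg$s_input),
                 mean(dg$s_output), tolerance = 1e-10)
  }
})

test_that("two-way ANOVA detects a condition effect, not an absent housing effect", {
  set.seed(9)
  tab <- generate_ieg_counts(seed = 101)
  dens <- ieg_density(tab)
  res <- two_way_anova_tukey(dens$per_animal, marker = "cFOS")
  expect_lt(res$p_condition, 0.05)
  expect_gt(res$p_housing, 0.0)
  expect_true(all(res$n_per_cell == 6))
  # housing-effect p-values are roughly uniform under the null:
  # rejection rate near alpha over seeds
  ph <- vapply(1:60, function(s) {
    d <- ieg_density(generate_ieg_counts(seed = 200 + s))
    two_way_anova_tukey(d$per_animal, marker = "NPAS4")$p_housing
  }, numeric(1))
  expect_lt(mean(ph < 0.05), 0.2)
  expect_gt(mean(ph), 0.25)   # not piled near zero
})

test_that("two-way ANOVA degenerate and validation behavior", {
  d <- expand.grid(animal_id = 1:4, group = c("SH", "EE"),
                   condition = c("HC", "NOE"))
  d$density <- 1
  expect_message(res <- two_way_anova_tukey(d), "zero variance")
  expect_equal(res$p_housing, 1)
  expect_equal(res$p_condition, 1)

  d2 <- d[!(d$group == "EE" & d$condition == "NOE"), ]
  expect_error(two_way_anova_tukey(d2), "design cell EE:NOE is empty")
})

test_that("relabeling housing groups leaves the ANOVA table invariant", {
  tab <- generate_ieg_counts(seed = 102)
  dens <- ieg_density(tab)$per_animal
  a <- two_way_anova_tukey(dens, marker = "cFOS")
  swapped <- dens
  swapped$group <- ifelse(swapped$group == "SH", "EE", "SH")
  b <- two_way_anova_tukey(swapped, marker = "cFOS")
  expect_equal(a$p_housing, b$p_housing)
  expect_equal(a$p_condition, b$p_condition)
  expect_equal(a$p_interaction, b$p_interaction)
})
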