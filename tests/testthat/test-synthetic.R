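test_that("generated input sets hit the correlation target and are reproducible", {
  s <- generate_input_set(seed = 71)
  expect_length(s$trains, 5)
  expect_equal(s$realized_r, 0.76, tolerance = 0.02 / 0.76)
  counts <- vapply(s$trains, n_spikes, integer(1))
  expect_true(all(counts >= 12 & counts <= 28))   # within 40% of 20

  # bit-reproducible under the same seed
  s2 <- generate_input_set(seed = 71)
  expect_identical(lapply(s$trains, `[[`, "times"),
                   lapply(s2$trains, `[[`, "times"))
  # config metadata travels with the result
  expect_equal(attr(s, "config")$target_r, 0.76)

  # the realized R is exactly what pairwise_input_similarity recomputes
  expect_equal(pairwise_input_similarity(s, "R", 0.01)$mean, s$realized_r)
})

test_that("copy probability 1 with no jitter yields identical trains", {
  set.seed(72)
  tt <- patsep:::draw_correlated_set(10, 2, 5, copy_p = 1, jitter_sd = 0)
  for (k in 2:5) expect_identical(tt[[k]], tt[[1]])
  expect_equal(patsep:::mean_pairwise_r_times(tt, 0.01, 2), 1)
})

test_that("thinning correlation matches the analytic oracle", {
  # with zero jitter the expected pairwise binned-count correlation of two
  # thinned children equals the copy probability, independent of bin width
  for (p in c(0.5, 0.76)) {
    set.seed(730 + round(100 * p))
    r_hat <- mean(replicate(2000, patsep:::mean_pairwise_r_times(
      patsep:::draw_correlated_set(10, 2, 2, copy_p = p, jitter_sd = 0),
      0.01, 2)), na.rm = TRUE)
    # small-sample Pearson bias at 200 bins is within the band
    expect_equal(r_hat, p, tolerance = 0.02 / p)
  }
})

test_that("simulated granule cells honor their configuration", {
  iset <- generate_input_set(seed = 74)
  rec <- simulate_granule_cell(iset, seed = 75)
  expect_s3_class(rec, "recording_set")
  expect_length(rec$outputs, 50)
  expect_equal(rec$n_repetitions, 10)

  ident <- identity_recording(iset)
  for (k in seq_along(ident$outputs))
    expect_identical(ident$outputs[[k]]$times,
                     ident$inputs[[ident$input_id[k]]]$times)

  silent <- simulate_granule_cell(iset, p_spike = 0, spontaneous_rate = 0,
                                  seed = 76)
  expect_true(all(vapply(silent$outputs, n_spikes, integer(1)) == 0L))

  # refractory period enforces a minimum inter-spike interval
  bursty <- simulate_granule_cell(iset, p_spike = 1, p_extra = 1,
                                  burst_lag = 0.003, refractory = 0.004,
                                  spontaneous_rate = 50, seed = 77)
  isis <- unlist(lapply(bursty$outputs, function(o) diff(o$times)))
  expect_true(all(isis > 0.004))
})

test_that("spike_probability recovers the simulated response probability", {
  iset <- generate_input_set(seed = 78)
  rec <- simulate_granule_cell(iset, p_spike = 0.5, p_extra = 0,
                               spontaneous_rate = 0, latency_mean = 0.004,
                               latency_sd = 0.001, seed = 79)
  sp <- spike_probability(rec)
  ci_half <- qnorm(0.995) * sqrt(0.25 / sp$n_stimuli)
  expect_lt(abs(sp$probability - 0.5), ci_half)
  expect_true(sp$qc_pass)
})

test_that("tracking traces respect speed, rest and attraction settings", {
  still <- generate_tracking_trace(duration = 30, mean_speed = 0,
                                   rest_fraction = 0, seed = 81)
  expect_equal(locomotion_summary(still)$total_distance_m, 0)

  # rest-bout fraction translates into immobile time
  pcts <- vapply(1:10, function(s) {
    tr <- generate_tracking_trace(duration = 300, rest_fraction = 0.3,
                                  seed = 810 + s)
    locomotion_summary(tr)$pct_time_mobile
  }, numeric(1))
  expect_lt(abs(mean(pcts) - 70), 5)

  # attraction toward a single object zone dominates exploration time
  layout <- object_layout(rbind(c(10, 10), c(30, 30),
                                c(10, 30), c(30, 10)), radius = 4)
  wins <- vapply(1:20, function(s) {
    tr <- generate_tracking_trace(duration = 240,
                                  attract_centers = rbind(c(10, 10)),
                                  attract_strength = 6, seed = 820 + s)
    oe <- object_exploration_time(tr, layout)
    oe$per_object[1] > max(oe$per_object[-1])
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  tr <- generate_tracking_trace(duration = 60, seed = 83)
  expect_identical(generate_tracking_trace(duration = 60, seed = 83)$x,
                   tr$x)
})

test_that("NOR cohorts and IEG tables have the configured structure", {
  coh <- generate_nor_cohort(seed = 84)
  expect_equal(nrow(coh), 24)
  expect_equal(coh$di,
               discrimination_index(coh$time_familiar, coh$time_novel))
  expect_equal(mean(coh$di), 0.66, tolerance = 0.1)

  # chance-level cohort: one-sample t-test rejects at about alpha
  set.seed(85)
  rej <- vapply(1:200, function(s) {
    c0 <- generate_nor_cohort(mean_di = 0.5, seed = 8500 + s)
    one_sample_t(c0$di[c0$group == "SH"], 0.5)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)

  tab <- generate_ieg_counts(seed = 86)
  expect_equal(nrow(tab), 2 * 2 * 6 * 2 * 12)
  expect_true(all(tab$positive_cells >= 0))
  expect_true(all(tab$gcl_area >= 1.5 & tab$gcl_area <= 2.5))

  # Poisson mean: density x area
  big <- generate_ieg_counts(density_hc = c(cFOS = 0.5),
                             density_noe = c(cFOS = 0.5),
                             n_animals = 1, images_per_animal = 10000,
                             area_range = c(2, 2), seed = 87)
  expect_equal(mean(big$positive_cells), 1.0, tolerance = 0.03)
})
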