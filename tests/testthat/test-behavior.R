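make_trace <- function(x, y, dt = 0.1, ...) {
  tracking_trace(seq(0, by = dt, length.out = length(x)), x, y, ...)
}

test_that("tracking trace validation", {
  expect_error(tracking_trace(c(0, 1, 1), c(1, 2, 3), c(1, 2, 3)),
               "strictly increasing")
  expect_error(tracking_trace(c(0, 1), c(1, 45), c(1, 2)), "arena")
  expect_error(tracking_trace(0, 1, 1), "two samples")
})

test_that("locomotion summary arithmetic", {
  # stationary trace
  tr <- make_trace(rep(20, 50), rep(20, 50))
  lo <- locomotion_summary(tr)
  expect_equal(lo$total_distance_m, 0)
  expect_equal(lo$pct_time_mobile, 0)

  # straight path: 40 cm in 10 s at 10 Hz
  tr <- make_trace(seq(0, 40, length.out = 101), rep(20, 101))
  lo <- locomotion_summary(tr)
  expect_equal(lo$total_distance_m, 0.4)
  expect_equal(lo$mean_speed_cm_s, 4)
  expect_equal(lo$pct_time_mobile, 100)

  # full circular lap: distance within 1% of 2*pi*r at 20 Hz
  th <- seq(0, 2 * pi, length.out = 20 * 10 + 1)
  r <- 15
  tr <- make_trace(20 + r * cos(th), 20 + r * sin(th), dt = 0.05)
  expect_equal(locomotion_summary(tr)$total_distance_m, 2 * pi * r / 100,
               tolerance = 0.01)

  # non-uniform sampling is rejected
  bad <- tracking_trace(c(0, 0.1, 0.5), c(1, 2, 3), c(1, 2, 3))
  expect_error(locomotion_summary(bad), "uniformly sampled")
})

test_that("locomotion distance is invariant under translation and rotation", {
  set.seed(13)
  x <- cumsum(rnorm(200, 0, 0.5)) + 20
  y <- cumsum(rnorm(200, 0, 0.5)) + 20
  stopifnot(all(x > 0 & x < 40 & y > 0 & y < 40))
  d0 <- locomotion_summary(make_trace(x, y))$total_distance_m
  d_shift <- locomotion_summary(make_trace(x + 3, y - 2))$total_distance_m
  # 90 degree rotation about the arena center
  d_rot <- locomotion_summary(make_trace(40 - y, x))$total_distance_m
  expect_equal(d_shift, d0)
  expect_equal(d_rot, d0)
})

test_that("zone times partition the trace duration exactly", {
  tr <- make_trace(rep(20, 100), rep(20, 100))   # parked in the center
  zt <- zone_times(tr)
  expect_equal(zt$pct_center, 100)

  wall <- make_trace(seq(1, 39, length.out = 100), rep(1, 100))
  zt <- zone_times(wall)
  expect_equal(zt$pct_periphery, 100)

  set.seed(14)
  x <- runif(500, 0, 40); y <- runif(500, 0, 40)
  tr <- make_trace(x, y)
  zt <- zone_times(tr)
  dur <- tr$t[length(tr$t)] - tr$t[1]
  expect_equal(zt$time_center_s + zt$time_periphery_s, dur,
               tolerance = 1e-9 / dur)
  expect_error(zone_times(tr, c(-5, 45, 0, 40)), "inside the arena")
})

test_that("object exploration assigns samples to the nearest zone", {
  layout <- object_layout(rbind(c(10, 10), c(30, 30)), radius = 4)
  away <- make_trace(rep(20, 100), rep(20, 100))
  oe <- object_exploration_time(away, layout)
  expect_equal(oe$total_s, 0)

  parked <- make_trace(rep(10, 301), rep(10, 301))
  oe <- object_exploration_time(parked, layout)
  expect_equal(unname(oe$per_object[1]), 30)
  expect_equal(unname(oe$per_object[2]), 0)

  # two symmetric visits give equal per-object times
  visit <- make_trace(c(rep(10, 50), rep(30, 50)),
                      c(rep(10, 50), rep(30, 50)))
  oe <- object_exploration_time(visit, layout)
  expect_lt(abs(oe$per_object[1] - oe$per_object[2]), 0.2)

  expect_warning(object_layout(rbind(c(10, 10), c(14, 10)), radius = 4),
                 "overlap")
  expect_error(object_layout(rbind(c(1, 1)), radius = 4), "inside the arena")
})

test_that("discrimination index arithmetic and label-swap symmetry", {
  expect_equal(discrimination_index(40, 60), 0.6)
  expect_equal(discrimination_index(30, 30), 0.5)
  expect_equal(discrimination_index(0, 12), 1)
  expect_message(di <- discrimination_index(0, 0), "zero total")
  expect_true(is.na(di))
  expect_error(discrimination_index(-1, 2), "non-negative")

  set.seed(15)
  f <- runif(20, 0, 60); n <- runif(20, 0, 60)
  expect_equal(discrimination_index(f, n) + discrimination_index(n, f),
               rep(1, 20))
})

test_that("IEG density arithmetic", {
  tab <- data.frame(animal_id = c("a1", "a1", "a2"), group = "SH",
                    condition = "NOE", marker = "cFOS",
                    positive_cells = c(2, 4, 12),
                    gcl_area = c(1, 1, 0.05))
  d <- ieg_density(tab)
  expect_equal(d$per_image$density, c(2, 4, 240))
  expect_equal(d$per_animal$density[d$per_animal$animal_id == "a1"], 3)
  expect_equal(d$group_summary$mean_density, mean(c(3, 240)))
  expect_equal(d$group_summary$n_animals, 2L)

  # zero-count image is retained with density 0; zero area is rejected
  tab2 <- rbind(tab, data.frame(animal_id = "a3", group = "SH",
                                condition = "NOE", marker = "cFOS",
                                positive_cells = c(0, 5),
                                gcl_area = c(2, 0)))
  expect_message(d2 <- ieg_density(tab2), "rejected")
  expect_equal(d2$n_rejected, 1L)
  expect_true(0 %in% d2$per_image$density)
})
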