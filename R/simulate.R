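# Synthetic-data generators: correlated Poisson input-train sets (by
# mother-train thinning with a calibrated copy probability), simulated
# granule-cell responders, arena trajectories, novel-object-recognition
# cohorts and immediate-early-gene count tables.  Every generator draws
# from a single seeded stream and attaches its configuration (including
# the seed) as the "config" attribute of its result.

# Evaluate an expression under a private RNG stream, restoring the caller's
# stream afterwards.  Used for calibration so that the calibrated copy
# probability is a pure function of the generator configuration.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# Draw one set of correlated trains: a mother Poisson train at rate
# rate/copy_p is thinned independently into each child (keep probability
# copy_p), then Gaussian latency jitter is applied per kept spike.  With
# zero jitter the pairwise binned-count correlation of two children is
# exactly copy_p in expectation, for any bin width (binomial thinning of a
# Poisson process) -- the closed-form oracle used in the tests.
draw_correlated_set <- function(rate, duration, n_trains, copy_p, jitter_sd) {
  n_mother <- stats::rpois(1L, rate / copy_p * duration)
  mother <- sort(stats::runif(n_mother, 0, duration))
  lapply(seq_len(n_trains), function(i) {
    keep <- mother[stats::runif(n_mother) < copy_p]
    if (jitter_sd > 0 && length(keep))
      keep <- keep + stats::rnorm(length(keep), 0, jitter_sd)
    keep <- keep[keep >= 0 & keep < duration]
    unique(sort(keep))
  })
}

mean_pairwise_r_times <- function(times_list, bin_width, duration) {
  nb <- n_bins_for(duration, bin_width)
  M <- t(vapply(times_list, function(tt)
    tabulate(pmin(floor(tt / bin_width), nb - 1L) + 1L, nbins = nb),
    integer(nb)))
  S <- suppressWarnings(stats::cor(t(M)))
  vals <- S[upper.tri(S)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

calib_cache <- new.env(parent = emptyenv())

# Calibrate the copy probability by bisection so that the expected mean
# pairwise Pearson correlation of a generated set, at the requested bin
# width and jitter, equals target_r.  Each probe is a Monte-Carlo average
# over n_eval_sets sets under a private, configuration-derived seed.
calibrate_copy_probability <- function(rate, duration, n_trains, target_r,
                                       bin_width, jitter_sd,
                                       n_eval_sets = 200L, n_iter = 14L) {
  key <- paste(rate, duration, n_trains, target_r, bin_width, jitter_sd,
               sep = "|")
  cached <- calib_cache[[key]]
  if (!is.null(cached)) return(cached)
  lo <- max(0.02, target_r - 0.15)
  hi <- min(0.99, target_r + 0.15)
  eval_r <- function(p) {
    vals <- replicate(n_eval_sets, mean_pairwise_r_times(
      draw_correlated_set(rate, duration, n_trains, p, jitter_sd),
      bin_width, duration))
    mean(vals, na.rm = TRUE)
  }
  p <- with_private_seed(sum(utf8ToInt(key)) %% 100000L + 1L, {
    r_lo <- eval_r(lo)
    r_hi <- eval_r(hi)
    if (r_lo > target_r || r_hi < target_r)
      stop(sprintf(paste0(
        "calibration failure: target R = %.3f unreachable at this ",
        "rate/bin (probe R at copy probability %.2f: %.3f; at %.2f: %.3f)"),
        target_r, lo, r_lo, hi, r_hi), call. = FALSE)
    a <- lo; b <- hi
    for (k in seq_len(n_iter)) {
      mid <- (a + b) / 2
      if (eval_r(mid) < target_r) a <- mid else b <- mid
    }
    (a + b) / 2
  })
  calib_cache[[key]] <- p
  p
}

#' Generate a set of correlated Poisson input trains
#'
#' Generates `n_trains` Poisson spike trains with a prescribed mean
#' pairwise Pearson correlation of their binned spike counts, emulating the
#' stimulation protocol's input sets (five 2-s, 10 Hz trains with mean
#' pairwise R of 0.76 at 10 ms bins).  The construction thins a common
#' mother Poisson train into each child with a calibrated copy probability
#' and applies small Gaussian latency jitter; candidate sets are then
#' rejection-sampled until the realized mean pairwise correlation lies
#' within `tolerance` of `target_r` and every train's spike count is within
#' 40% of `rate * duration`.
#'
#' @param rate Target firing rate of each train in Hz (default 10).
#' @param duration Train duration in seconds (default 2).
#' @param n_trains Number of trains per set (default 5).
#' @param target_r Target mean pairwise Pearson correlation at `bin_width`
#'   (default 0.76).
#' @param bin_width Bin width in seconds at which the correlation target is
#'   defined (default 0.01).
#' @param tolerance Acceptance band around `target_r` for the realized mean
#'   pairwise correlation (default 0.02).
#' @param jitter_sd Gaussian latency jitter applied to each copied spike,
#'   in seconds (default 0.001); the calibration absorbs its decorrelating
#'   effect.
#' @param seed Integer seed for reproducibility (optional).
#' @param max_reject Maximum number of candidate sets before giving up
#'   (default 10000).
#' @return An object of class `input_set`: `trains` (list of
#'   [spike_train()]), `realized_r`, `copy_prob`, `n_rejected`; the full
#'   configuration is attached as attribute `"config"`.
#' @examples
#' s <- generate_input_set(seed = 42)
#' s$realized_r
#' @export
generate_input_set <- function(rate = 10, duration = 2, n_trains = 5,
                               target_r = 0.76, bin_width = 0.01,
                               tolerance = 0.02, jitter_sd = 0.001,
                               seed = NULL, max_reject = 10000) {
  stopifnot(rate > 0, duration > 0, n_trains >= 2,
            target_r > 0, target_r < 1, tolerance > 0, jitter_sd >= 0)
  copy_p <- calibrate_copy_probability(rate, duration, n_trains, target_r,
                                       bin_width, jitter_sd)
  if (!is.null(seed)) set.seed(seed)
  count_lo <- 0.6 * rate * duration
  count_hi <- 1.4 * rate * duration
  n_rejected <- 0L
  repeat {
    times <- draw_correlated_set(rate, duration, n_trains, copy_p,
                                 jitter_sd)
    counts <- lengths(times)
    if (all(counts >= count_lo & counts <= count_hi)) {
      r <- mean_pairwise_r_times(times, bin_width, duration)
      if (is.finite(r) && abs(r - target_r) <= tolerance) break
    }
    n_rejected <- n_rejected + 1L
    if (n_rejected >= max_reject)
      stop(sprintf("no acceptable set within %d candidates (target %.3f +/- %.3f)",
                   max_reject, target_r, tolerance), call. = FALSE)
  }
  trains <- lapply(seq_len(n_trains), function(i)
    spike_train(times[[i]], duration, sprintf("input-%d", i)))
  res <- structure(
    list(trains = trains, realized_r = r, copy_prob = copy_p,
         n_rejected = n_rejected),
    class = "input_set")
  attr(res, "config") <- list(
    rate = rate, duration = duration, n_trains = n_trains,
    target_r = target_r, bin_width = bin_width, tolerance = tolerance,
    jitter_sd = jitter_sd, seed = seed)
  res
}

#' @export
print.input_set <- function(x, ...) {
  cat(sprintf("<input_set> %d trains, realized mean pairwise R = %.3f (copy probability %.3f, %d rejections)\n",
              length(x$trains), x$realized_r, x$copy_prob, x$n_rejected))
  invisible(x)
}

#' Simulate a granule-cell recording
#'
#' A phenomenological spiking responder standing in for a whole-cell
#' current-clamp recording: each input spike evokes an output spike with
#' probability `p_spike` at a Gaussian latency (truncated at 0); with
#' probability `p_extra` a doublet spike follows at `burst_lag`; an
#' independent Poisson background at `spontaneous_rate` is superimposed;
#' spikes closer than `refractory` to the previous kept spike are dropped.
#' With `p_spike = 1`, zero latency, no extras, no background and zero
#' refractory period the responder is the identity: every output sweep
#' equals its input train.
#'
#' @param inputs An `input_set` or list of `spike_train` input trains.
#' @param p_spike Per-stimulus response probability (default 0.55; the
#'   recording protocol targets 0.3-0.8).
#' @param latency_mean,latency_sd Response latency distribution in seconds
#'   (defaults 0.005 and 0.002).
#' @param p_extra Probability of a doublet spike per responded stimulus
#'   (default 0.2).
#' @param burst_lag Doublet lag in seconds (default 0.003, a typical
#'   intra-burst interval).
#' @param refractory Absolute refractory period in seconds (default 0.002).
#' @param spontaneous_rate Background Poisson rate in Hz (default 0.2).
#' @param n_repetitions Repetitions of the full input set (default 10,
#'   giving 50 sweeps for a 5-train set).
#' @param cell_id,group Metadata for the resulting [recording_set()].
#' @param seed Integer seed (optional).
#' @return A [recording_set()]; the configuration is attached as attribute
#'   `"config"`.
#' @export
simulate_granule_cell <- function(inputs, p_spike = 0.55,
                                  latency_mean = 0.005, latency_sd = 0.002,
                                  p_extra = 0.2, burst_lag = 0.003,
                                  refractory = 0.002,
                                  spontaneous_rate = 0.2,
                                  n_repetitions = 10,
                                  cell_id = "cell-1", group = "SH",
                                  seed = NULL) {
  if (inherits(inputs, "input_set")) inputs <- inputs$trains
  stopifnot(is.list(inputs),
            all(vapply(inputs, inherits, logical(1), "spike_train")),
            p_spike >= 0, p_spike <= 1, p_extra >= 0, p_extra <= 1,
            latency_sd >= 0, refractory >= 0, spontaneous_rate >= 0,
            n_repetitions >= 1)
  if (!is.null(seed)) set.seed(seed)
  duration <- inputs[[1L]]$duration
  outputs <- list(); oid <- integer(); orep <- integer()
  apply_refractory <- function(tt) {
    tt <- sort(tt)
    keep <- numeric(0)
    last <- -Inf
    for (s in tt) {
      if (s > last + refractory) {   # strict: also drops exact duplicates
        keep <- c(keep, s)
        last <- s
      }
    }
    keep
  }
  for (r in seq_len(n_repetitions)) {
    for (i in seq_along(inputs)) {
      stim <- inputs[[i]]$times
      responded <- stim[stats::runif(length(stim)) < p_spike]
      lat <- stats::rnorm(length(responded), latency_mean, latency_sd)
      lat[lat < 0] <- 0
      spikes <- responded + lat
      if (p_extra > 0 && length(spikes)) {
        extra <- spikes[stats::runif(length(spikes)) < p_extra] + burst_lag
        spikes <- c(spikes, extra)
      }
      if (spontaneous_rate > 0) {
        nb <- stats::rpois(1L, spontaneous_rate * duration)
        spikes <- c(spikes, stats::runif(nb, 0, duration))
      }
      spikes <- spikes[spikes >= 0 & spikes < duration]
      spikes <- apply_refractory(spikes)
      outputs[[length(outputs) + 1L]] <-
        spike_train(spikes, duration, sprintf("out-i%d-r%d", i, r))
      oid <- c(oid, i); orep <- c(orep, r)
    }
  }
  rec <- recording_set(cell_id, group, inputs, outputs, oid, orep)
  attr(rec, "config") <- list(
    p_spike = p_spike, latency_mean = latency_mean,
    latency_sd = latency_sd, p_extra = p_extra, burst_lag = burst_lag,
    refractory = refractory, spontaneous_rate = spontaneous_rate,
    n_repetitions = n_repetitions, seed = seed)
  rec
}

#' Generate an arena tracking trace
#'
#' Simulates a trajectory inside the arena as an Ornstein-Uhlenbeck
#' velocity walk with reflecting walls, interleaved rest bouts (a two-state
#' Markov chain with prescribed stationary rest fraction), and optional
#' drift toward attraction points (object zones).  With zero speed and no
#' attraction the trace is stationary.
#'
#' @param duration Trace duration in seconds (default 600).
#' @param dt Sampling interval in seconds (default 0.1, i.e. 10 Hz).
#' @param arena Arena side lengths in cm.
#' @param mean_speed Mean speed while mobile, cm/s (default 8).
#' @param tau Velocity autocorrelation time in seconds (default 1).
#' @param rest_fraction Stationary fraction of time at rest in `[0, 1)`
#'   (default 0.2).
#' @param mean_rest_bout Mean rest-bout duration in seconds (default 2).
#' @param attract_centers Optional matrix of (x, y) attraction points.
#' @param attract_strength Drift speed toward the nearest attraction point,
#'   cm/s (default 0).
#' @param animal_id,group,age_band Metadata.
#' @param seed Integer seed (optional).
#' @return A [tracking_trace()]; the configuration is attached as attribute
#'   `"config"`.
#' @export
generate_tracking_trace <- function(duration = 600, dt = 0.1,
                                    arena = c(40, 40), mean_speed = 8,
                                    tau = 1, rest_fraction = 0.2,
                                    mean_rest_bout = 2,
                                    attract_centers = NULL,
                                    attract_strength = 0,
                                    animal_id = "m1", group = "SH",
                                    age_band = NA_character_,
                                    seed = NULL) {
  stopifnot(dt > 0, duration > dt, mean_speed >= 0,
            rest_fraction >= 0, rest_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  s_v <- mean_speed / sqrt(pi / 2)   # per-component sd giving this mean speed
  a <- exp(-dt / tau)
  b <- s_v * sqrt(1 - a^2)
  if (!is.null(attract_centers)) attract_centers <- as.matrix(attract_centers)
  p_rest_to_move <- min(1, dt / mean_rest_bout)
  p_move_to_rest <- if (rest_fraction > 0)
    min(1, dt / (mean_rest_bout * (1 - rest_fraction) / rest_fraction))
  else 0
  x <- numeric(n); y <- numeric(n)
  x[1L] <- stats::runif(1, 0.1, 0.9) * arena[1L]
  y[1L] <- stats::runif(1, 0.1, 0.9) * arena[2L]
  v <- stats::rnorm(2L, 0, s_v)
  resting <- stats::runif(1) < rest_fraction
  reflect <- function(p, lim) {
    while (p < 0 || p > lim) {
      if (p < 0) p <- -p
      if (p > lim) p <- 2 * lim - p
    }
    p
  }
  for (k in 2L:n) {
    if (resting) {
      if (stats::runif(1) < p_rest_to_move) {
        resting <- FALSE
        v <- stats::rnorm(2L, 0, s_v)
      }
    } else if (stats::runif(1) < p_move_to_rest) {
      resting <- TRUE
    }
    if (resting) {
      x[k] <- x[k - 1L]; y[k] <- y[k - 1L]
    } else {
      v <- a * v + b * stats::rnorm(2L)
      drift <- c(0, 0)
      if (!is.null(attract_centers) && attract_strength > 0) {
        dv <- cbind(attract_centers[, 1L] - x[k - 1L],
                    attract_centers[, 2L] - y[k - 1L])
        dd <- sqrt(rowSums(dv^2))
        j <- which.min(dd)
        if (dd[j] > 1e-6) drift <- attract_strength * dv[j, ] / dd[j]
      }
      x[k] <- reflect(x[k - 1L] + (v[1L] + drift[1L]) * dt, arena[1L])
      y[k] <- reflect(y[k - 1L] + (v[2L] + drift[2L]) * dt, arena[2L])
    }
  }
  tr <- tracking_trace(t, x, y, animal_id, group, age_band, arena)
  attr(tr, "config") <- list(
    duration = duration, dt = dt, arena = arena, mean_speed = mean_speed,
    tau = tau, rest_fraction = rest_fraction,
    mean_rest_bout = mean_rest_bout,
    attract_strength = attract_strength, seed = seed)
  tr
}

#' Generate a novel-object-recognition cohort
#'
#' Draws per-animal exploration times such that the realized discrimination
#' index is Gaussian around `mean_di` (truncated to `[0, 1]`), with total
#' exploration time Gaussian around `mean_total`.
#'
#' @param n_per_group Animals per group (default 12).
#' @param mean_di Mean discrimination index (default 0.66, a typical value
#'   for juveniles that discriminate; use 0.5 for a chance-level cohort).
#' @param sd_di Standard deviation of the index (default 0.1).
#' @param mean_total,sd_total Total object-exploration time distribution in
#'   seconds (defaults 60 and 15, floored at 5 s).
#' @param groups Group labels (default `c("SH", "EE")`).
#' @param seed Integer seed (optional).
#' @return A data frame with `animal_id`, `group`, `time_familiar`,
#'   `time_novel`, `di`; configuration attached as attribute `"config"`.
#' @export
generate_nor_cohort <- function(n_per_group = 12, mean_di = 0.66,
                                sd_di = 0.1, mean_total = 60,
                                sd_total = 15, groups = c("SH", "EE"),
                                seed = NULL) {
  stopifnot(n_per_group >= 1, sd_di >= 0, sd_total >= 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(groups, function(g) {
    di <- pmin(1, pmax(0, stats::rnorm(n_per_group, mean_di, sd_di)))
    total <- pmax(5, stats::rnorm(n_per_group, mean_total, sd_total))
    data.frame(animal_id = sprintf("%s-%02d", g, seq_len(n_per_group)),
               group = g, time_familiar = (1 - di) * total,
               time_novel = di * total, di = di,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "config") <- list(n_per_group = n_per_group, mean_di = mean_di,
                              sd_di = sd_di, mean_total = mean_total,
                              sd_total = sd_total, seed = seed)
  res
}

#' Generate an immediate-early-gene count table
#'
#' Per-image positive-cell counts are Poisson with mean `area * density`,
#' where the density is set per (housing group, condition) cell of the
#' design: by default a behavioral-task effect (novel-object exploration
#' raises the density above home cage) and no housing effect.  Default
#' densities follow typical sparse granule-cell recruitment (well below one
#' positive cell per mm^2).
#'
#' @param density_hc,density_noe Named vectors of home-cage and
#'   novel-object-exploration densities (cells/mm^2) per marker.
#' @param housing_effect Additive density shift for the EE group
#'   (default 0).
#' @param n_animals Animals per housing-by-condition cell (default 6).
#' @param images_per_animal Images per animal (default 12).
#' @param area_range Uniform range of per-image granule-cell-layer mask
#'   areas in mm^2 (default `c(1.5, 2.5)`).
#' @param seed Integer seed (optional).
#' @return A data frame with `animal_id`, `group`, `condition`, `marker`,
#'   `image_id`, `positive_cells`, `gcl_area`; configuration attached as
#'   attribute `"config"`.
#' @export
generate_ieg_counts <- function(density_hc = c(cFOS = 0.31, NPAS4 = 0.20),
                                density_noe = c(cFOS = 0.63, NPAS4 = 0.43),
                                housing_effect = 0,
                                n_animals = 6, images_per_animal = 12,
                                area_range = c(1.5, 2.5), seed = NULL) {
  stopifnot(n_animals >= 1, images_per_animal >= 1,
            identical(sort(names(density_hc)), sort(names(density_noe))))
  if (!is.null(seed)) set.seed(seed)
  markers <- names(density_hc)
  rows <- list()
  for (g in c("SH", "EE")) {
    for (cond in c("HC", "NOE")) {
      base <- if (cond == "HC") density_hc else density_noe
      for (an in seq_len(n_animals)) {
        aid <- sprintf("%s-%s-%02d", g, cond, an)
        for (m in markers) {
          dens <- max(0, base[[m]] + if (g == "EE") housing_effect else 0)
          area <- stats::runif(images_per_animal, area_range[1L],
                               area_range[2L])
          cnt <- stats::rpois(images_per_animal, area * dens)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = aid, group = g, condition = cond, marker = m,
            image_id = seq_len(images_per_animal),
            positive_cells = cnt, gcl_area = area,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "config") <- list(density_hc = density_hc,
                              density_noe = density_noe,
                              housing_effect = housing_effect,
                              n_animals = n_animals,
                              images_per_animal = images_per_animal,
                              area_range = area_range, seed = seed)
  res
}
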