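# Behavioral analyses: arena tracking metrics (open field / novel object
# exploration), the novel-object-recognition discrimination index, and
# immediate-early-gene cell densities.

#' Construct a tracking trace
#'
#' A uniformly sampled trajectory of one animal inside a square arena
#' (default 40 x 40 cm).  Timestamps must be strictly increasing and the
#' coordinates inside the arena bounds.
#'
#' @param t Timestamps in seconds.
#' @param x,y Coordinates in cm.
#' @param animal_id,group,age_band Metadata (group `SH`/`EE`; age band
#'   e.g. `"P19-P21"` or `"P25-P27"`).
#' @param arena Arena side lengths in cm, `c(width, height)`.
#' @return An object of class `tracking_trace`.
#' @export
tracking_trace <- function(t, x, y, animal_id = "", group = "SH",
                           age_band = NA_character_, arena = c(40, 40)) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y))
    stop("`t`, `x`, `y` must have equal length", call. = FALSE)
  if (length(t) < 2L)
    stop("a trace needs at least two samples", call. = FALSE)
  if (anyNA(t) || is.unsorted(t, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (anyNA(x) || anyNA(y) ||
      any(x < 0 | x > arena[1L] | y < 0 | y > arena[2L]))
    stop("coordinates must lie inside the arena bounds", call. = FALSE)
  structure(list(t = t, x = x, y = y,
                 animal_id = as.character(animal_id)[1L],
                 group = as.character(group)[1L],
                 age_band = as.character(age_band)[1L],
                 arena = as.numeric(arena)),
            class = "tracking_trace")
}

#' @export
print.tracking_trace <- function(x, ...) {
  cat(sprintf("<tracking_trace> %s (%s): %d samples over %.1f s in a %g x %g cm arena\n",
              x$animal_id, x$group, length(x$t), x$t[length(x$t)] - x$t[1L],
              x$arena[1L], x$arena[2L]))
  invisible(x)
}

check_uniform_dt <- function(trace) {
  dt <- diff(trace$t)
  if (any(dt <= 0) || max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt))
    stop("trace must be uniformly sampled with increasing timestamps",
         call. = FALSE)
  dt
}

#' Locomotion summary of a tracking trace
#'
#' @param trace A [tracking_trace()].
#' @param mobility_threshold Speed threshold in cm/s above which a step
#'   counts as mobile (default 2, a typical tracking-software setting).
#' @return A list with `total_distance_m`, `mean_speed_cm_s` (total
#'   distance over trace duration), `time_mobile_s` and `pct_time_mobile`.
#' @export
locomotion_summary <- function(trace, mobility_threshold = 2) {
  stopifnot(inherits(trace, "tracking_trace"))
  dt <- check_uniform_dt(trace)
  step <- sqrt(diff(trace$x)^2 + diff(trace$y)^2)
  speed <- step / dt
  duration <- trace$t[length(trace$t)] - trace$t[1L]
  mobile <- speed >= mobility_threshold
  list(total_distance_m = sum(step) / 100,
       mean_speed_cm_s = sum(step) / duration,
       time_mobile_s = sum(dt[mobile]),
       pct_time_mobile = 100 * sum(dt[mobile]) / duration)
}

#' Center/periphery dwell times
#'
#' Sample-weighted dwell time in a rectangular center zone versus the
#' periphery; each inter-sample interval is attributed to the position at
#' its start, so center and periphery times partition the trace duration
#' exactly.
#'
#' @param trace A [tracking_trace()].
#' @param center_zone Rectangle `c(xmin, xmax, ymin, ymax)` in cm, strictly
#'   inside the arena.  Default: the central 50% of each side (a 20 x 20 cm
#'   zone covering 25% of a 40 x 40 cm arena).
#' @return A list with `time_center_s`, `time_periphery_s`, `pct_center`,
#'   `pct_periphery`.
#' @export
zone_times <- function(trace, center_zone = NULL) {
  stopifnot(inherits(trace, "tracking_trace"))
  if (is.null(center_zone))
    center_zone <- c(trace$arena[1L] * c(0.25, 0.75),
                     trace$arena[2L] * c(0.25, 0.75))
  if (center_zone[1L] < 0 || center_zone[2L] > trace$arena[1L] ||
      center_zone[3L] < 0 || center_zone[4L] > trace$arena[2L] ||
      center_zone[1L] >= center_zone[2L] || center_zone[3L] >= center_zone[4L])
    stop("`center_zone` must be a valid rectangle inside the arena",
         call. = FALSE)
  dt <- diff(trace$t)
  n <- length(trace$t)
  inside <- trace$x[-n] >= center_zone[1L] & trace$x[-n] <= center_zone[2L] &
    trace$y[-n] >= center_zone[3L] & trace$y[-n] <= center_zone[4L]
  duration <- trace$t[n] - trace$t[1L]
  tc <- sum(dt[inside])
  list(time_center_s = tc, time_periphery_s = duration - tc,
       pct_center = 100 * tc / duration,
       pct_periphery = 100 * (duration - tc) / duration)
}

#' Define an object layout in the arena
#'
#' @param centers A matrix (or data frame) with one row per object and
#'   columns x, y in cm.
#' @param radius Exploration-zone radius around each object center in cm
#'   (default 4: a 2 cm margin around a 2 cm object-boundary proxy).
#' @param arena Arena side lengths in cm.
#' @return An object of class `object_layout`.
#' @export
object_layout <- function(centers, radius = 4, arena = c(40, 40)) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || !nrow(centers))
    stop("`centers` must have one (x, y) row per object", call. = FALSE)
  if (any(centers[, 1L] < radius | centers[, 1L] > arena[1L] - radius |
          centers[, 2L] < radius | centers[, 2L] > arena[2L] - radius))
    stop("object zones must lie inside the arena", call. = FALSE)
  if (nrow(centers) > 1L) {
    dmin <- min(stats::dist(centers))
    if (dmin < 2 * radius)
      warning(sprintf("object centers are %.1f cm apart (< 2 x radius); zones overlap, samples go to the nearest center",
                      dmin), call. = FALSE)
  }
  structure(list(centers = centers, radius = radius, arena = arena),
            class = "object_layout")
}

#' Per-object exploration times
#'
#' Sample-weighted dwell time inside the exploration zone of each object;
#' a sample inside overlapping zones is attributed to the nearest object
#' center.
#'
#' @param trace A [tracking_trace()].
#' @param layout An [object_layout()].
#' @return A list with `per_object` (seconds, one entry per object) and
#'   `total_s`.
#' @export
object_exploration_time <- function(trace, layout) {
  stopifnot(inherits(trace, "tracking_trace"),
            inherits(layout, "object_layout"))
  dt <- diff(trace$t)
  n <- length(trace$t)
  px <- trace$x[-n]; py <- trace$y[-n]
  d2 <- sapply(seq_len(nrow(layout$centers)), function(k)
    (px - layout$centers[k, 1L])^2 + (py - layout$centers[k, 2L])^2)
  d2 <- matrix(d2, ncol = nrow(layout$centers))
  nearest <- max.col(-d2, ties.method = "first")
  in_zone <- d2[cbind(seq_along(nearest), nearest)] <= layout$radius^2
  per_object <- vapply(seq_len(nrow(layout$centers)), function(k)
    sum(dt[in_zone & nearest == k]), numeric(1))
  names(per_object) <- paste0("object_", seq_along(per_object))
  list(per_object = per_object, total_s = sum(per_object))
}

#' Novel-object-recognition discrimination index
#'
#' The ratio of time spent exploring the novel object over the total time
#' exploring both objects; 0.5 is chance level, values above 0.5 indicate
#' preference for the novel object.
#'
#' @param time_familiar,time_novel Non-negative exploration times in
#'   seconds (vectorized; trials are paired elementwise).
#' @return Discrimination index in `[0, 1]`; `NA` (with a message) for
#'   trials with zero total exploration, which must be excluded.
#' @examples
#' discrimination_index(40, 60)  # 0.6
#' @export
discrimination_index <- function(time_familiar, time_novel) {
  time_familiar <- as.numeric(time_familiar)
  time_novel <- as.numeric(time_novel)
  if (any(time_familiar < 0, na.rm = TRUE) ||
      any(time_novel < 0, na.rm = TRUE))
    stop("exploration times must be non-negative", call. = FALSE)
  total <- time_familiar + time_novel
  di <- ifelse(total > 0, time_novel / total, NA_real_)
  if (any(is.na(di)))
    message(sum(is.na(di)),
            " trial(s) with zero total exploration excluded (DI undefined)")
  di
}

#' Immediate-early-gene cell densities
#'
#' Converts per-image positive-cell counts over granule-cell-layer areas
#' into densities (cells/mm^2), averages them per animal, and summarizes
#' per (housing group, condition, marker) cell of the design.  Rows with a
#' non-positive area are rejected with a message.
#'
#' @param table A data frame with columns `animal_id`, `group`,
#'   `condition`, `marker`, `positive_cells`, `gcl_area` (mm^2), and
#'   optionally `image_id`.
#' @return A list of class `ieg_density` with `per_image`, `per_animal`
#'   (mean density per animal) and `group_summary` (mean of animal means
#'   with `n_animals`), plus `n_rejected`.
#' @export
ieg_density <- function(table) {
  required <- c("animal_id", "group", "condition", "marker",
                "positive_cells", "gcl_area")
  stopifnot(is.data.frame(table))
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(table$positive_cells < 0, na.rm = TRUE))
    stop("`positive_cells` must be non-negative", call. = FALSE)
  bad <- !is.finite(table$gcl_area) | table$gcl_area <= 0
  if (any(bad))
    message(sum(bad), " row(s) with non-positive area rejected")
  d <- table[!bad, , drop = FALSE]
  if (!nrow(d)) stop("no usable rows", call. = FALSE)
  d$density <- d$positive_cells / d$gcl_area
  per_animal <- stats::aggregate(
    density ~ animal_id + group + condition + marker, data = d, FUN = mean)
  group_summary <- stats::aggregate(
    density ~ group + condition + marker, data = per_animal, FUN = mean)
  names(group_summary)[names(group_summary) == "density"] <- "mean_density"
  n_animals <- stats::aggregate(
    animal_id ~ group + condition + marker, data = per_animal,
    FUN = function(a) length(unique(a)))
  names(n_animals)[names(n_animals) == "animal_id"] <- "n_animals"
  group_summary <- merge(group_summary, n_animals,
                         by = c("group", "condition", "marker"))
  structure(list(per_image = d, per_animal = per_animal,
                 group_summary = group_summary,
                 n_rejected = sum(bad)),
            class = "ieg_density")
}

#' @export
print.ieg_density <- function(x, ...) {
  cat("IEG densities (cells/mm^2), mean of per-animal means:\n")
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}
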