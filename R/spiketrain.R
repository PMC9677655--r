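#' Construct a spike train
#'
#' A spike train is an ordered set of spike times recorded (or generated)
#' within a sweep of fixed duration.  Times are in seconds, must be strictly
#' increasing and lie in `[0, duration)`; a spike at exactly `t = duration`
#' is rejected so that binning is unambiguous.  Empty trains are valid.
#'
#' @param times Numeric vector of spike times in seconds.
#' @param duration Sweep duration in seconds (a single positive number).
#' @param label Free-text identifier.
#' @return An object of class `spike_train` with fields `times`, `duration`
#'   and `label`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 1.9), duration = 2)
#' n_spikes(st)
#' @export
spike_train <- function(times = numeric(), duration, label = "") {
  times <- as.numeric(times)
  duration <- as.numeric(duration)
  if (length(duration) != 1L || !is.finite(duration) || duration <= 0)
    stop("`duration` must be a single positive number", call. = FALSE)
  if (anyNA(times))
    stop("spike times must not contain NA", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (length(times) && (times[1L] < 0 || times[length(times)] >= duration))
    stop("spike times must lie in [0, duration)", call. = FALSE)
  structure(
    list(times = times, duration = duration,
         label = as.character(label)[1L]),
    class = "spike_train"
  )
}

#' Number of spikes in a spike train
#' @param train A `spike_train`.
#' @return Integer spike count.
#' @export
n_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train%s> %d spikes over %g s\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              length(x$times), x$duration))
  invisible(x)
}

# Number of bins for a duration/width pair.  A ragged final bin is allowed
# for widths that do not divide the duration; near-integer ratios are
# snapped so that e.g. 2 s / 0.01 s is exactly 200 bins despite floating
# point representation of the width.
n_bins_for <- function(duration, bin_width) {
  ratio <- duration / bin_width
  if (abs(ratio - round(ratio)) < 1e-9) {
    as.integer(round(ratio))
  } else {
    as.integer(ceiling(ratio))
  }
}

#' Construct a binned spike-count vector
#'
#' @param counts Non-negative integer counts, one per bin.
#' @param bin_width Bin width in seconds.
#' @param duration Sweep duration in seconds; `length(counts)` must equal
#'   `ceiling(duration / bin_width)`.
#' @return An object of class `binned_train`.
#' @export
binned_train <- function(counts, bin_width, duration) {
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("`counts` must be non-negative integers", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  nb <- n_bins_for(duration, bin_width)
  if (length(counts) != nb)
    stop(sprintf("`counts` has length %d but %d bins are expected for duration %g at width %g",
                 length(counts), nb, duration, bin_width), call. = FALSE)
  structure(
    list(counts = counts, bin_width = bin_width, duration = duration),
    class = "binned_train"
  )
}

#' @export
print.binned_train <- function(x, ...) {
  cat(sprintf("<binned_train> %d bins of %g s, %d spikes\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Bin a spike train into spike counts
#'
#' Bins are half-open intervals `[k*w, (k+1)*w)` with 0-based index `k`, so a
#' spike exactly on an interior bin edge belongs to the higher bin.  The
#' total spike count is conserved.  For a `bin_width` that does not divide
#' the duration the final bin is ragged (shorter than `bin_width`).
#'
#' @param train A `spike_train`.
#' @param bin_width Bin width in seconds; must be positive and no larger
#'   than the train duration.
#' @return A `binned_train` with `ceiling(duration / bin_width)` bins.
#' @examples
#' st <- spike_train(c(0.005, 0.012, 0.9995), duration = 2)
#' b <- bin_spike_train(st, 0.01)
#' sum(b$counts) == n_spikes(st)
#' @export
bin_spike_train <- function(train, bin_width) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  if (bin_width > train$duration)
    stop("`bin_width` must not exceed the train duration", call. = FALSE)
  nb <- n_bins_for(train$duration, bin_width)
  # pmin guards against a division rounding exactly to nb for times just
  # below duration
  idx <- pmin(floor(train$times / bin_width), nb - 1L)
  counts <- tabulate(idx + 1L, nbins = nb)
  binned_train(counts, bin_width, train$duration)
}

#' Assemble a single-cell recording set
#'
#' One recording set holds the stimulation inputs of one granule-cell
#' recording (typically five 2-s, 10 Hz Poisson trains) together with the
#' evoked output sweeps, each labeled by the input train that produced it
#' and the repetition number.  Under the standard protocol of 10 repetitions
#' of 5 trains there are 50 output sweeps.
#'
#' @param cell_id Cell identifier.
#' @param group Housing group, `"SH"` (standard housing) or `"EE"`
#'   (enriched environment).
#' @param inputs List of `spike_train` input trains (length >= 2; the
#'   standard protocol uses 5).
#' @param outputs List of `spike_train` output sweeps.
#' @param input_id Integer vector, parallel to `outputs`: index of the input
#'   train that evoked each sweep.
#' @param repetition Integer vector, parallel to `outputs`: repetition
#'   number of each sweep (1-based).
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(cell_id, group, inputs, outputs = list(),
                          input_id = integer(), repetition = integer()) {
  group <- match.arg(group, c("SH", "EE"))
  if (!is.list(inputs) || length(inputs) < 2L ||
      !all(vapply(inputs, inherits, logical(1), "spike_train")))
    stop("`inputs` must be a list of at least two spike_train objects",
         call. = FALSE)
  if (!is.list(outputs) ||
      !all(vapply(outputs, inherits, logical(1), "spike_train")))
    stop("`outputs` must be a list of spike_train objects", call. = FALSE)
  input_id <- as.integer(input_id)
  repetition <- as.integer(repetition)
  if (length(input_id) != length(outputs) ||
      length(repetition) != length(outputs))
    stop("`input_id` and `repetition` must be parallel to `outputs`",
         call. = FALSE)
  if (length(input_id) &&
      (anyNA(input_id) || any(input_id < 1L) ||
       any(input_id > length(inputs))))
    stop("`input_id` values must index into `inputs`", call. = FALSE)
  if (length(repetition) && (anyNA(repetition) || any(repetition < 1L)))
    stop("`repetition` values must be positive integers", call. = FALSE)
  key <- paste(input_id, repetition)
  if (anyDuplicated(key))
    stop("each (input_id, repetition) pair may occur at most once",
         call. = FALSE)
  durs <- vapply(c(inputs, outputs), function(tr) tr$duration, numeric(1))
  if (length(unique(durs)) > 1L)
    stop("all trains in a recording set must share one duration",
         call. = FALSE)
  structure(
    list(cell_id = as.character(cell_id)[1L], group = group,
         inputs = inputs, outputs = outputs,
         input_id = input_id, repetition = repetition,
         n_repetitions = if (length(repetition)) max(repetition) else 0L,
         duration = durs[1L]),
    class = "recording_set"
  )
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> cell %s (%s): %d input trains, %d output sweeps (%d repetitions)\n",
              x$cell_id, x$group, length(x$inputs), length(x$outputs),
              x$n_repetitions))
  invisible(x)
}
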