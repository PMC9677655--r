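# Spike-pattern statistics of recorded output sweeps: firing rate, burst
# probability, compactness/occupancy and their dispersion across sweeps,
# and the per-stimulus spike-probability quality control.

# Per-stimulus response windows.  Each input spike at time t opens the
# window [t, min(t + cap, next input spike, duration)): the window always
# closes at the next stimulus so a response is attributed to exactly one
# stimulus.
response_windows <- function(input, cap) {
  if (!length(input$times))
    stop("input train has no stimuli", call. = FALSE)
  starts <- input$times
  ends <- pmin(starts + cap,
               c(starts[-1L], input$duration),
               input$duration)
  cbind(start = starts, end = ends)
}

count_in_windows <- function(output, windows) {
  t_out <- output$times
  vapply(seq_len(nrow(windows)), function(k)
    sum(t_out >= windows[k, 1L] & t_out < windows[k, 2L]), integer(1))
}

#' Firing rate of a recording's output sweeps
#'
#' Firing rate is defined as the number of spikes per sweep; the rate in Hz
#' is the count divided by the sweep duration.
#'
#' @param rec A [recording_set()] with at least one output sweep.
#' @return A list with `per_sweep` (data frame of `input_id`, `repetition`,
#'   `n_spikes`, `rate_hz`), `mean_spikes_per_sweep` and `mean_rate_hz`.
#' @export
firing_rate <- function(rec) {
  stopifnot(inherits(rec, "recording_set"))
  if (!length(rec$outputs))
    stop("recording has no output sweeps", call. = FALSE)
  counts <- vapply(rec$outputs, n_spikes, integer(1))
  per_sweep <- data.frame(
    input_id = rec$input_id, repetition = rec$repetition,
    n_spikes = counts, rate_hz = counts / rec$duration
  )
  list(per_sweep = per_sweep,
       mean_spikes_per_sweep = mean(counts),
       mean_rate_hz = mean(counts) / rec$duration)
}

#' Burst probability of one output sweep
#'
#' The probability that a single stimulus elicits a small burst: a stimulus
#' counts as bursting when at least two output spikes fall in its response
#' window (which extends from the stimulus to the earliest of
#' `burst_window_cap`, the next stimulus, or the sweep end).
#'
#' @param output Output `spike_train` of one sweep.
#' @param input The `spike_train` of stimuli that evoked it (non-empty).
#' @param burst_window_cap Maximum response-window length in seconds
#'   (default 0.05; at 10 Hz Poisson stimulation the median inter-stimulus
#'   interval is about 69 ms, so most windows are cap-limited).
#' @return Fraction of stimuli that elicited a burst, in `[0, 1]`.
#' @export
p_burst <- function(output, input, burst_window_cap = 0.05) {
  stopifnot(inherits(output, "spike_train"), inherits(input, "spike_train"))
  w <- response_windows(input, burst_window_cap)
  mean(count_in_windows(output, w) >= 2L)
}

#' Cell-level burst probability
#'
#' Mean of [p_burst()] over all output sweeps of a recording, each sweep
#' evaluated against the input train that evoked it.
#'
#' @param rec A [recording_set()] with at least one output sweep.
#' @inheritParams p_burst
#' @return A single probability in `[0, 1]`.
#' @export
cell_p_burst <- function(rec, burst_window_cap = 0.05) {
  stopifnot(inherits(rec, "recording_set"))
  if (!length(rec$outputs))
    stop("recording has no output sweeps", call. = FALSE)
  vals <- vapply(seq_along(rec$outputs), function(k)
    p_burst(rec$outputs[[k]], rec$inputs[[rec$input_id[k]]],
            burst_window_cap), numeric(1))
  mean(vals)
}

#' Compactness of a binned spike train
#'
#' The fraction of bins occupied by at least one spike; a compact (sparse)
#' train concentrates its spikes in few bins.
#'
#' @param b A `binned_train`.
#' @return A value in `[0, 1]` (0 for an empty train).
#' @export
compactness <- function(b) {
  stopifnot(inherits(b, "binned_train"))
  mean(b$counts > 0L)
}

#' Occupancy of a binned spike train
#'
#' The mean number of spikes per occupied bin; together with
#' [compactness()] it describes how burst-like the within-train spike
#' distribution is.
#'
#' @param b A `binned_train`.
#' @return A value `>= 1`, or `NA` for an empty train (occupancy is then
#'   undefined).
#' @export
occupancy <- function(b) {
  stopifnot(inherits(b, "binned_train"))
  occ <- sum(b$counts > 0L)
  if (occ == 0L) return(NA_real_)
  sum(b$counts) / occ
}

#' Dispersion of spike-pattern statistics across a recording's sweeps
#'
#' Summarizes how variable the output spike patterns are across sweeps:
#' the mean binwise compactness, and the variation of occupancy and firing
#' rate across sweeps.  Variation is operationalized as the mean absolute
#' pairwise difference over all sweep pairs (`method = "mapd"`); a
#' coefficient-of-variation alternative is available (`method = "cv"`).
#' Empty sweeps have undefined occupancy and are excluded from the
#' occupancy pairs; their number is reported.
#'
#' @param rec A [recording_set()] with at least two output sweeps.
#' @param bin_width Bin width in seconds (default 0.01).
#' @param method `"mapd"` (mean absolute pairwise difference, default) or
#'   `"cv"` (coefficient of variation).
#' @return A list with `binwise_compactness`, `occupancy_variation`,
#'   `fr_variation`, `n_sweeps`, `n_empty_excluded` and `method`.
#' @export
dispersion_summary <- function(rec, bin_width = 0.01,
                               method = c("mapd", "cv")) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "recording_set"))
  if (length(rec$outputs) < 2L)
    stop("dispersion requires at least two output sweeps", call. = FALSE)
  binned <- lapply(rec$outputs, bin_spike_train, bin_width = bin_width)
  comp <- vapply(binned, compactness, numeric(1))
  occ <- vapply(binned, occupancy, numeric(1))
  fr <- vapply(rec$outputs, n_spikes, integer(1))
  variation <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    if (method == "mapd") mean(stats::dist(x, method = "manhattan"))
    else if (mean(x) == 0) NA_real_ else stats::sd(x) / mean(x)
  }
  list(binwise_compactness = mean(comp),
       occupancy_variation = variation(occ),
       fr_variation = variation(as.numeric(fr)),
       n_sweeps = length(rec$outputs),
       n_empty_excluded = sum(is.na(occ)),
       method = method)
}

#' Per-stimulus spike probability and quality control
#'
#' The fraction of stimuli, pooled over all output sweeps, whose response
#' window (as in [p_burst()]) contains at least one output spike.  The
#' recording protocol targets a per-stimulus spike probability between 30%
#' and 80%; recordings outside that range fail quality control and should
#' be excluded from group summaries.
#'
#' @param rec A [recording_set()] with at least one output sweep.
#' @param response_window_cap Maximum response-window length in seconds
#'   (default 0.05).
#' @param qc_range Acceptance range for the probability (default
#'   `c(0.3, 0.8)`).
#' @return A list with `probability`, `qc_pass`, `n_stimuli` and
#'   `n_responded`.
#' @export
spike_probability <- function(rec, response_window_cap = 0.05,
                              qc_range = c(0.3, 0.8)) {
  stopifnot(inherits(rec, "recording_set"))
  if (!length(rec$outputs))
    stop("recording has no output sweeps", call. = FALSE)
  n_stim <- 0L; n_resp <- 0L
  for (k in seq_along(rec$outputs)) {
    w <- response_windows(rec$inputs[[rec$input_id[k]]],
                          response_window_cap)
    cnt <- count_in_windows(rec$outputs[[k]], w)
    n_stim <- n_stim + nrow(w)
    n_resp <- n_resp + sum(cnt >= 1L)
  }
  prob <- n_resp / n_stim
  list(probability = prob,
       qc_pass = prob >= qc_range[1L] && prob <= qc_range[2L],
       n_stimuli = n_stim, n_responded = n_resp)
}
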