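# Pairwise similarity metrics on binned spike-count vectors.
#
# All three metrics share an undefined-value policy: a pair for which the
# metric does not exist (zero variance for Pearson, zero norm for NDP/SF)
# returns NA_real_, and every summary excludes NA pairs and reports how
# many were excluded.  Silent exclusion would bias means for sparse trains,
# where empty sweeps are common.

check_same_binning <- function(a, b) {
  if (!inherits(a, "binned_train") || !inherits(b, "binned_train"))
    stop("both arguments must be binned_train objects", call. = FALSE)
  if (a$bin_width != b$bin_width || length(a$counts) != length(b$counts))
    stop("trains must share the same bin width and bin count", call. = FALSE)
  invisible(TRUE)
}

#' Pearson correlation of two binned spike trains
#'
#' @param a,b `binned_train` objects with identical binning.
#' @return The Pearson correlation coefficient of the two count vectors, or
#'   `NA` when either vector has zero variance (the correlation is then
#'   undefined; such pairs are excluded from all summaries).
#' @examples
#' a <- binned_train(c(1, 0, 2, 1), 0.5, 2)
#' b <- binned_train(c(0, 1, 1, 2), 0.5, 2)
#' pearson_r(a, b)   # 0
#' @export
pearson_r <- function(a, b) {
  check_same_binning(a, b)
  x <- as.numeric(a$counts); y <- as.numeric(b$counts)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Normalized dot product (cosine similarity) of two binned spike trains
#'
#' The cosine of the angle between the two count vectors: 1 for colinear
#' vectors, 0 for orthogonal vectors (no co-occupied bin).  Measures how far
#' the output pattern is orthogonalized relative to the input.
#'
#' @inheritParams pearson_r
#' @return A value in `[0, 1]`, or `NA` when either train is empty.
#' @export
ndp <- function(a, b) {
  check_same_binning(a, b)
  x <- as.numeric(a$counts); y <- as.numeric(b$counts)
  na <- sqrt(sum(x^2)); nb <- sqrt(sum(y^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(x * y) / (na * nb)
}

#' Scaling factor of two binned spike trains
#'
#' The ratio of the smaller to the larger Euclidean norm of the two count
#' vectors.  SF is symmetric, lies in `(0, 1]`, and equals 1 when the two
#' trains have equal norms; values below 1 indicate that the number of
#' spikes per bin is scaled up or down between the trains.
#'
#' @inheritParams pearson_r
#' @return A value in `(0, 1]`, or `NA` when either train is empty.
#' @export
scaling_factor <- function(a, b) {
  check_same_binning(a, b)
  na <- sqrt(sum(as.numeric(a$counts)^2))
  nb <- sqrt(sum(as.numeric(b$counts)^2))
  if (na == 0 || nb == 0) return(NA_real_)
  min(na, nb) / max(na, nb)
}

# All-pairs metric matrix over the rows of a count matrix.  Undefined
# entries are NA.  Using one matrix for inputs and outputs together keeps
# input and output similarities on an identical code path, so an identity
# responder lands exactly on the diagonal.
metric_matrix <- function(M, metric = c("R", "NDP", "SF")) {
  metric <- match.arg(metric)
  storage.mode(M) <- "double"
  if (metric == "R") {
    v <- apply(M, 1L, stats::var)
    S <- suppressWarnings(stats::cor(t(M)))
    S[!is.finite(S)] <- NA_real_
    S[v == 0, ] <- NA_real_
    S[, v == 0] <- NA_real_
  } else {
    nrm <- sqrt(rowSums(M^2))
    if (metric == "NDP") {
      S <- tcrossprod(M) / outer(nrm, nrm)
    } else {
      S <- outer(nrm, nrm, pmin) / outer(nrm, nrm, pmax)
    }
    S[nrm == 0, ] <- NA_real_
    S[, nrm == 0] <- NA_real_
  }
  S
}

bin_counts_matrix <- function(trains, bin_width) {
  durs <- vapply(trains, function(tr) tr$duration, numeric(1))
  if (length(unique(durs)) > 1L)
    stop("trains must share one duration", call. = FALSE)
  nb <- n_bins_for(durs[1L], bin_width)
  M <- t(vapply(trains, function(tr)
    bin_spike_train(tr, bin_width)$counts, integer(nb)))
  M
}

#' Pairwise similarity among a set of input trains
#'
#' Computes one similarity value per unordered pair of input trains (10
#' values for the standard 5-train set) at the given bin width.
#'
#' @param inputs A list of `spike_train` objects or an `input_set` as
#'   returned by [generate_input_set()].
#' @param metric One of `"R"` (Pearson correlation), `"NDP"` (normalized
#'   dot product) or `"SF"` (scaling factor).
#' @param bin_width Bin width in seconds (default 0.01, the 10 ms
#'   convention of the stimulation protocol).
#' @return A list with `pairs` (data frame of `i`, `j`, `value`), `mean`
#'   (over defined pairs), `n_undefined`, `metric` and `bin_width`.
#' @export
pairwise_input_similarity <- function(inputs, metric = c("R", "NDP", "SF"),
                                      bin_width = 0.01) {
  metric <- match.arg(metric)
  if (inherits(inputs, "input_set")) inputs <- inputs$trains
  if (!is.list(inputs) || length(inputs) < 2L)
    stop("`inputs` must be a list of at least two spike trains",
         call. = FALSE)
  M <- bin_counts_matrix(inputs, bin_width)
  S <- metric_matrix(M, metric)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1L], j = idx[, 2L],
                      value = S[idx])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       mean = mean(pairs$value, na.rm = TRUE),
       n_undefined = sum(is.na(pairs$value)),
       metric = metric, bin_width = bin_width)
}

#' Input/output similarity of a recording set
#'
#' For each unordered pair of input trains `(i, j)` the input similarity is
#' the metric between the two input trains, and the output similarity is
#' the mean of the metric over all cross pairs of their evoked sweeps (one
#' sweep of input `i` against one sweep of input `j`; 100 comparisons under
#' the standard 10-repetition protocol).  Output sweeps of the same input
#' are never compared here; see [output_reliability()] for that diagnostic.
#' Points with output similarity below input similarity indicate pattern
#' separation; points above indicate pattern convergence.
#'
#' @param rec A [recording_set()].
#' @param metric One of `"R"`, `"NDP"`, `"SF"`.
#' @param bin_width Bin width in seconds (default 0.01).
#' @return A data frame with one row per input pair: `cell_id`, `group`,
#'   `metric`, `bin_width`, `input_i`, `input_j`, `s_input`, `s_output`,
#'   `n_output_pairs` (cross pairs compared), `n_undefined_output`
#'   (undefined cross pairs, excluded from the mean), and `incomplete`
#'   (`TRUE` when either input has no sweeps).
#' @export
input_output_similarity <- function(rec, metric = c("R", "NDP", "SF"),
                                    bin_width = 0.01) {
  metric <- match.arg(metric)
  stopifnot(inherits(rec, "recording_set"))
  n_in <- length(rec$inputs)
  M <- bin_counts_matrix(c(rec$inputs, rec$outputs), bin_width)
  S <- metric_matrix(M, metric)
  out_rows <- lapply(seq_len(n_in), function(i)
    n_in + which(rec$input_id == i))
  combs <- utils::combn(n_in, 2L)
  res <- lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1L, k]; j <- combs[2L, k]
    ri <- out_rows[[i]]; rj <- out_rows[[j]]
    vals <- as.numeric(S[ri, rj])
    data.frame(
      cell_id = rec$cell_id, group = rec$group, metric = metric,
      bin_width = bin_width, input_i = i, input_j = j,
      s_input = S[i, j],
      s_output = if (length(vals) && any(!is.na(vals)))
        mean(vals[!is.na(vals)]) else NA_real_,
      n_output_pairs = length(vals),
      n_undefined_output = sum(is.na(vals)),
      incomplete = length(ri) == 0L || length(rj) == 0L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Within-input output reliability of a recording set
#'
#' Similarity of output sweeps evoked by repetitions of the *same* input
#' train, a reliability diagnostic complementary to
#' [input_output_similarity()] (which only compares sweeps across different
#' inputs).
#'
#' @inheritParams input_output_similarity
#' @return A data frame with one row per input train: `input_id`,
#'   `mean_similarity`, `n_pairs`, `n_undefined`.
#' @export
output_reliability <- function(rec, metric = c("R", "NDP", "SF"),
                               bin_width = 0.01) {
  metric <- match.arg(metric)
  stopifnot(inherits(rec, "recording_set"))
  if (!length(rec$outputs))
    stop("recording has no output sweeps", call. = FALSE)
  M <- bin_counts_matrix(rec$outputs, bin_width)
  S <- metric_matrix(M, metric)
  res <- lapply(sort(unique(rec$input_id)), function(i) {
    rows <- which(rec$input_id == i)
    if (length(rows) < 2L)
      return(data.frame(input_id = i, mean_similarity = NA_real_,
                        n_pairs = 0L, n_undefined = 0L))
    Si <- S[rows, rows]
    vals <- Si[upper.tri(Si)]
    data.frame(input_id = i,
               mean_similarity = mean(vals, na.rm = TRUE),
               n_pairs = length(vals),
               n_undefined = sum(is.na(vals)))
  })
  do.call(rbind, res)
}

#' Summarize pattern separation over a set of similarity points
#'
#' @param pairs A data frame of input/output similarity rows as produced by
#'   [input_output_similarity()] (possibly pooled over cells).
#' @return A list with `mean_s_input`, `mean_s_output` (defined pairs
#'   only), `fraction_below_diagonal` (share of defined pairs with output
#'   similarity strictly below input similarity, i.e. pattern-separating
#'   pairs), `n_pairs` and `n_excluded`.
#' @export
separation_summary <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0,
            all(c("s_input", "s_output") %in% names(pairs)))
  ok <- !is.na(pairs$s_input) & !is.na(pairs$s_output)
  if (!any(ok))
    stop("all similarity pairs are undefined", call. = FALSE)
  list(
    mean_s_input = mean(pairs$s_input[ok]),
    mean_s_output = mean(pairs$s_output[ok]),
    fraction_below_diagonal =
      mean(pairs$s_output[ok] < pairs$s_input[ok]),
    n_pairs = sum(ok),
    n_excluded = sum(!ok)
  )
}
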