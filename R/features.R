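#' Firing-rate and burstiness features of single spike trains
#'
#' * `firing_rate()` — spike count divided by sweep duration, Hz.
#' * `compactness()` — `1 - (occupied bins / total bins)` at a given time
#'   scale: 0 when every bin holds a spike; the maximum for a non-empty
#'   train, `1 - 1/N`, is reached when all spikes share one bin.
#' * `occupancy()` — mean number of spikes per occupied bin; at least 1,
#'   with 1 meaning every spike sits in its own bin.
#'
#' All three are undefined for empty trains (error): empty sweeps are
#' excluded upstream.
#'
#' @param train A non-empty [spike_train()].
#' @param tau_w_ms Bin width, ms.
#' @return A single numeric value.
#' @examples
#' st <- spike_train(seq(0.1, 1.9, length.out = 21))
#' firing_rate(st)              # 10.5 Hz
#' occupancy(st, tau_w_ms = 2000)  # one bin: equals the spike count
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (is_empty_train(train)) stop("empty train: excluded from features",
                                  call. = FALSE)
  n_spikes(train) / train$duration
}

#' @rdname firing_rate
#' @export
compactness <- function(train, tau_w_ms) {
  counts <- bin_counts_nonempty(train, tau_w_ms)
  1 - sum(counts > 0L) / length(counts)
}

#' @rdname firing_rate
#' @export
occupancy <- function(train, tau_w_ms) {
  counts <- bin_counts_nonempty(train, tau_w_ms)
  sum(counts) / sum(counts > 0L)
}

bin_counts_nonempty <- function(train, tau_w_ms) {
  stopifnot(inherits(train, "spike_train"))
  if (is_empty_train(train)) stop("empty train: excluded from features",
                                  call. = FALSE)
  bin_train(train, tau_w_ms)
}

#' Per-train feature table for a recording set
#'
#' Computes firing rate, Compactness and Occupancy for every parent train
#' and sweep of a recording set, at one or more time scales. Empty sweeps
#' are omitted (their ids are reported in the `excluded` attribute).
#'
#' @param rec A [recording_set()].
#' @param tau_w_ms Vector of bin widths, ms.
#' @return A data frame with columns `role` (input/output), `id`, `parent`,
#'   `firing_rate_hz`, then `compactness_<tau>` / `occupancy_<tau>` per
#'   time scale.
#' @export
train_features <- function(rec, tau_w_ms = 10) {
  stopifnot(inherits(rec, "recording_set"))
  all_trains <- c(rec$input$trains, rec$sweeps)
  roles <- c(rep("input", length(rec$input$trains)),
             rep("output", length(rec$sweeps)))
  parents <- c(seq_along(rec$input$trains), rec$parent_of)
  keep <- !vapply(all_trains, is_empty_train, TRUE)
  df <- data.frame(role = roles[keep], id = seq_along(all_trains)[keep],
                   parent = parents[keep],
                   firing_rate_hz = vapply(all_trains[keep], firing_rate, 0))
  for (tw in tau_w_ms) {
    df[[sprintf("compactness_%g", tw)]] <-
      vapply(all_trains[keep], compactness, 0, tau_w_ms = tw)
    df[[sprintf("occupancy_%g", tw)]] <-
      vapply(all_trains[keep], occupancy, 0, tau_w_ms = tw)
  }
  attr(df, "excluded") <- seq_along(all_trains)[!keep]
  df
}

#' Burst probability of a recording set
#'
#' The probability of firing more than one output spike between two
#' consecutive input pulses, pooled over all sweeps of the set (each
#' sweep's spikes are attributed to the inter-pulse intervals of its own
#' parent train; the final interval extends to the sweep end).
#'
#' @param rec A [recording_set()].
#' @return The pooled burst probability (a single number in [0, 1]).
#' @export
p_burst <- function(rec) {
  pulse_response_stats(rec)$p_burst
}

#' Median-normalized inter-spike-interval distribution
#'
#' Pools the inter-spike intervals (ISIs, computed within each train) of a
#' collection of spike trains, normalizes them to the median pooled ISI,
#' and discretizes the normalized values into 250 equal bins spanning
#' [0, 50]. Normalized ISIs above 50 are counted as overflow and dropped
#' from the histogram.
#'
#' @param trains List of [spike_train()] objects (trains with fewer than
#'   two spikes contribute no ISIs).
#' @param n_bins,range_max Discretization (defaults 250 bins over [0, 50]).
#' @return A list with `probabilities` (length `n_bins`, summing to 1),
#'   `breaks`, `n_isis` and `overflow_count`.
#' @export
isi_distribution <- function(trains, n_bins = 250, range_max = 50) {
  isis <- unlist(lapply(trains, function(t) diff(t$times)))
  if (length(isis) < 2L) {
    stop("need at least two inter-spike intervals", call. = FALSE)
  }
  norm <- isis / stats::median(isis)
  overflow <- sum(norm > range_max)
  norm <- norm[norm <= range_max]
  breaks <- seq(0, range_max, length.out = n_bins + 1L)
  idx <- findInterval(norm, breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  list(probabilities = counts / sum(counts), breaks = breaks,
       n_isis = length(isis), overflow_count = overflow)
}

#' Kullback-Leibler burstiness of an output set
#'
#' Quantifies how far the ISI statistics of an output set diverge from a
#' reference (Poisson-like) input population: `D_KL(M || P)` where `M` is
#' the median-normalized ISI distribution pooled over the output trains
#' and `P` the one pooled over the reference input trains of the matching
#' rate class. Both distributions use the fixed 250-bin [0, 50] grid.
#'
#' Zero bins are handled by additive smoothing: `epsilon` (default
#' `1/(4 * n_isis * n_bins)`, with `n_isis` the smaller of the two pooled
#' counts) is added to every bin of both distributions before
#' renormalizing, which keeps the divergence finite and converges to the
#' unsmoothed value as data grow. The natural logarithm is used.
#'
#' @param output_trains List of output [spike_train()]s (typically the 50
#'   sweeps of a recording set).
#' @param reference_trains List of reference input trains (pooled across
#'   the input sets of the matching rate class).
#' @param epsilon Smoothing constant; `NULL` for the default above.
#' @param n_bins,range_max Passed to [isi_distribution()].
#' @return The divergence in nats (non-negative; 0 iff the smoothed
#'   distributions coincide).
#' @export
kl_burstiness <- function(output_trains, reference_trains, epsilon = NULL,
                          n_bins = 250, range_max = 50) {
  m_dist <- isi_distribution(output_trains, n_bins, range_max)
  p_dist <- isi_distribution(reference_trains, n_bins, range_max)
  kl_divergence(m_dist$probabilities, p_dist$probabilities,
                epsilon = if (is.null(epsilon)) {
                  1 / (4 * min(m_dist$n_isis, p_dist$n_isis) * n_bins)
                } else epsilon)
}

#' @rdname kl_burstiness
#' @param m,p Probability vectors of equal length (will be smoothed and
#'   renormalized).
#' @export
kl_divergence <- function(m, p, epsilon = 1e-6) {
  if (length(m) != length(p)) stop("distributions must have equal length",
                                   call. = FALSE)
  m <- (m + epsilon) / sum(m + epsilon)
  p <- (p + epsilon) / sum(p + epsilon)
  sum(m * log(m / p))
}
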