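#' Generate a homogeneous Poisson spike train
#'
#' Draws a homogeneous Poisson process on `[0, duration)`: the spike count
#' is Poisson(`rate_hz * duration`) and spike times are independent
#' uniforms, sorted. Ties (probability zero in theory, possible only through
#' floating-point coincidence) are re-drawn.
#'
#' @param rate_hz Mean firing rate in Hz (> 0).
#' @param duration Sweep length in seconds.
#' @return A [spike_train()].
#' @examples
#' set.seed(1)
#' n_spikes(gen_poisson_train(10))
#' @export
gen_poisson_train <- function(rate_hz, duration = 2) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("'rate_hz' must be a single positive rate", call. = FALSE)
  }
  n <- stats::rpois(1L, rate_hz * duration)
  times <- sort(stats::runif(n, 0, duration))
  while (any(duplicated(times))) {
    times <- sort(c(times[!duplicated(times)],
                    stats::runif(sum(duplicated(times)), 0, duration)))
  }
  spike_train(times, duration)
}

mean_pairwise_r <- function(trains, tau_w_ms = 10) {
  cv <- vapply(trains, function(t) as.numeric(bin_train(t, tau_w_ms)),
               numeric(length(bin_train(trains[[1]], tau_w_ms))))
  cm <- suppressWarnings(stats::cor(cv))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}

#' Generate a correlated Poisson input set
#'
#' Builds `n_trains` Poisson-like spike trains whose mean pairwise Pearson
#' correlation between 10-ms spike-count vectors is tuned to `target_r`.
#' Construction: one reference Poisson train is drawn; every train keeps
#' each reference spike with probability `p` (shared spikes are exact
#' copies) and adds an independent Poisson stream of private spikes that
#' restores the requested rate. Under this scheme the pairwise correlation
#' is approximately `p^2`, and `p` is tuned by bisection against the
#' correlation actually measured on the generated trains (common random
#' numbers keep the map monotone), followed by a local refinement pass that
#' moves single private spikes into or out of reference bins while the
#' measured error decreases.
#'
#' `target_r = 1` short-circuits to identical copies of one Poisson train
#' (achieved correlation exactly 1).
#'
#' @param target_r Target mean pairwise correlation at `tau_w_ms`, in [0, 1].
#' @param n_trains Number of trains (5 or 10).
#' @param rate_hz Firing rate of every train, Hz.
#' @param duration Sweep length, s.
#' @param tau_w_ms Bin width at which the correlation target is defined.
#' @param tol Acceptable |achieved - target| (default 0.02).
#' @param max_iter Bisection + refinement iteration cap.
#' @param design Design label stored on the set.
#' @return An [input_set()] whose `report` lists the achieved mean pairwise
#'   correlation, its pairwise spread, and iterations used.
#' @export
gen_correlated_set <- function(target_r, n_trains = 5, rate_hz = 10,
                               duration = 2, tau_w_ms = 10, tol = 0.02,
                               max_iter = 40, design = "P10Hz") {
  if (target_r < 0 || target_r > 1) stop("'target_r' must be in [0, 1]",
                                         call. = FALSE)
  # designed stimuli hold their nominal rate: condition realized counts to
  # within 12% of rate * duration (rejection on the Poisson draw)
  nominal <- rate_hz * duration
  draw_count <- function() {
    repeat {
      n <- stats::rpois(1L, nominal)
      if (abs(n - nominal) <= 0.12 * nominal) return(n)
    }
  }
  ref <- gen_poisson_train(rate_hz, duration)
  while (abs(n_spikes(ref) - nominal) > 0.12 * nominal) {
    ref <- gen_poisson_train(rate_hz, duration)
  }
  if (target_r == 1) {
    trains <- replicate(n_trains, ref, simplify = FALSE)
    return(input_set(trains, design = design, target_r = 1,
                     report = list(achieved_r = 1, spread = 0, iterations = 0)))
  }
  n_ref <- n_spikes(ref)
  # common random numbers: fixed per-train keep-marks, private-spike pools
  # and target counts, so the p -> achieved-R map is monotone for bisection
  keep_marks <- matrix(stats::runif(n_trains * max(n_ref, 1L)),
                       nrow = n_trains)
  target_counts <- vapply(seq_len(n_trains), function(j) draw_count(), 0L)
  pools <- replicate(n_trains, {
    tt <- stats::runif(2L * ceiling(nominal), 0, duration)
    tt[order(stats::runif(length(tt)))]  # pool in fixed random order
  }, simplify = FALSE)

  realize <- function(p) {
    lapply(seq_len(n_trains), function(j) {
      kept <- if (n_ref) ref$times[keep_marks[j, seq_len(n_ref)] < p]
              else numeric(0)
      need <- max(0L, target_counts[j] - length(kept))
      priv <- pools[[j]][seq_len(min(need, length(pools[[j]])))]
      times <- sort(unique(c(kept, priv)))
      spike_train(times, duration)
    })
  }

  lo <- 0; hi <- 1; it <- 0
  best <- NULL; best_err <- Inf; best_p <- NA_real_
  repeat {
    it <- it + 1L
    p <- (lo + hi) / 2
    trains <- realize(p)
    r <- mean_pairwise_r(trains, tau_w_ms)
    err <- abs(r - target_r)
    if (err < best_err) { best <- trains; best_err <- err; best_p <- p }
    if (err <= tol / 2 || it >= max_iter) break
    if (r < target_r) lo <- p else hi <- p
  }
  trains <- best
  achieved <- mean_pairwise_r(trains, tau_w_ms)

  # local refinement: nudge single spikes toward/away from reference times
  refine_it <- 0
  while (abs(achieved - target_r) > tol / 2 && refine_it < max_iter &&
         n_ref > 0) {
    refine_it <- refine_it + 1L
    j <- sample.int(n_trains, 1L)
    cand <- trains[[j]]$times
    if (!length(cand)) break
    k <- sample.int(length(cand), 1L)
    new_times <- cand
    if (achieved < target_r) {
      new_times[k] <- ref$times[sample.int(n_ref, 1L)]  # align with reference
    } else {
      new_times[k] <- stats::runif(1L, 0, duration)     # scatter
    }
    if (anyDuplicated(new_times)) next  # keep spike counts intact
    trial <- trains
    trial[[j]] <- spike_train(sort(new_times), duration)
    r_new <- mean_pairwise_r(trial, tau_w_ms)
    if (abs(r_new - target_r) < abs(achieved - target_r)) {
      trains <- trial
      achieved <- r_new
    }
  }

  if (abs(achieved - target_r) > max(tol, 3 * tol)) {
    stop(sprintf(paste0("correlation tuning failed to converge: target %.3f, ",
                        "best achieved %.3f after %d iterations"),
                 target_r, achieved, it + refine_it), call. = FALSE)
  }
  cv <- vapply(trains, function(t) as.numeric(bin_train(t, tau_w_ms)),
               numeric(round(1000 * duration / tau_w_ms)))
  cm <- suppressWarnings(stats::cor(cv))
  pair_r <- cm[upper.tri(cm)]
  input_set(trains, design = design, target_r = target_r,
            report = list(achieved_r = achieved,
                          spread = stats::sd(pair_r),
                          pairwise_r = pair_r,
                          p_share = best_p,
                          iterations = it + refine_it))
}

#' Generate a rate-varying correlated input set (input set A)
#'
#' Ten Poisson trains with firing rates increasing linearly from
#' `rate_min_hz` to `rate_max_hz` while the mean pairwise correlation at
#' 10 ms is held near `target_r` (default 0.75). Because Poisson marginals
#' bound how correlated trains with very different rates can be, the trains
#' are built by coupled thinning of one reference train at the maximum
#' rate: each reference spike carries a shared uniform mark, and train `k`
#' keeps the spikes whose mark falls below `rate_k / rate_max`. Fully
#' shared marks give the maximally correlated (comonotone) coupling;
#' redrawing each mark independently with probability `1 - w` interpolates
#' toward independent thinning. The weight `w` is tuned by bisection
#' against the measured mean pairwise correlation.
#'
#' @param target_r Target mean pairwise correlation at `tau_w_ms`.
#' @param rate_min_hz,rate_max_hz Rate range, Hz (defaults 7 and 31.5).
#' @param n_trains Number of trains (default 10).
#' @param duration Sweep length, s.
#' @param tau_w_ms Bin width for the correlation target, ms.
#' @param tol,max_iter Convergence control as in [gen_correlated_set()].
#' @return An [input_set()] with design `"PdFR"` and a generation report.
#' @export
gen_varying_rate_set <- function(target_r = 0.75, rate_min_hz = 7,
                                 rate_max_hz = 31.5, n_trains = 10,
                                 duration = 2, tau_w_ms = 10, tol = 0.02,
                                 max_iter = 40) {
  rates <- seq(rate_min_hz, rate_max_hz, length.out = n_trains)
  q <- rates / rate_max_hz
  ref <- gen_poisson_train(rate_max_hz, duration)
  n_ref <- n_spikes(ref)
  shared <- stats::runif(n_ref)
  fresh <- matrix(stats::runif(n_trains * max(n_ref, 1L)), nrow = n_trains)
  use_shared_marks <- matrix(stats::runif(n_trains * max(n_ref, 1L)),
                             nrow = n_trains)

  realize <- function(w) {
    lapply(seq_len(n_trains), function(j) {
      if (!n_ref) return(spike_train(numeric(0), duration))
      mk <- ifelse(use_shared_marks[j, seq_len(n_ref)] < w,
                   shared, fresh[j, seq_len(n_ref)])
      spike_train(ref$times[mk < q[j]], duration)
    })
  }

  lo <- 0; hi <- 1; it <- 0
  best <- NULL; best_err <- Inf
  repeat {
    it <- it + 1L
    w <- (lo + hi) / 2
    trains <- realize(w)
    r <- mean_pairwise_r(trains, tau_w_ms)
    err <- abs(r - target_r)
    if (err < best_err) { best <- trains; best_err <- err }
    if (err <= tol / 2 || it >= max_iter) break
    if (r < target_r) lo <- w else hi <- w
  }
  trains <- best
  achieved <- mean_pairwise_r(trains, tau_w_ms)
  if (abs(achieved - target_r) > 3 * tol) {
    stop(sprintf(paste0("correlation tuning failed to converge: target %.3f, ",
                        "best achieved %.3f"), target_r, achieved),
         call. = FALSE)
  }
  input_set(trains, design = "PdFR", target_r = target_r,
            report = list(achieved_r = achieved, rates_hz = rates,
                          iterations = it))
}

#' Generate a fixed-rate bursty input set (input set B)
#'
#' Ten trains with the same spike count (default 21 spikes over 2 s, i.e.
#' 10.5 Hz each) but varying burstiness: train `k` places its spikes in
#' exactly `occupied_bins[k]` distinct construction bins, chosen uniformly
#' without replacement, with spike times uniform within each chosen bin.
#' Every chosen bin receives at least one spike; the remaining spikes are
#' spread uniformly over the chosen bins. Tied times are re-drawn.
#'
#' @param occupied_bins Integer vector, one entry per train: number of
#'   construction bins each train occupies. Defaults to
#'   `seq(3, 21, by = 2)` — from tightly clustered to one-spike-per-bin.
#' @param n_spikes_per_train Spike count common to all trains (default 21).
#' @param bin_ms Construction bin width, ms (default 10).
#' @param duration Sweep length, s.
#' @return An [input_set()] with design `"B10.5Hz"`.
#' @export
gen_bursty_set <- function(occupied_bins = seq(3, 21, by = 2),
                           n_spikes_per_train = 21, bin_ms = 10,
                           duration = 2) {
  n_bins <- floor(duration * 1000 / bin_ms)
  if (any(occupied_bins > n_bins)) {
    stop("occupied_bins exceeds the number of construction bins",
         call. = FALSE)
  }
  if (any(occupied_bins > n_spikes_per_train)) {
    stop("occupied_bins cannot exceed the spike count", call. = FALSE)
  }
  if (any(occupied_bins < 1)) stop("occupied_bins must be >= 1", call. = FALSE)
  w <- bin_ms / 1000
  trains <- lapply(occupied_bins, function(k) {
    bins <- sample.int(n_bins, k) - 1L
    # each chosen bin gets one spike; the surplus is spread uniformly
    assign_bins <- c(bins, bins[sample.int(k, n_spikes_per_train - k,
                                           replace = TRUE)])
    times <- assign_bins * w + stats::runif(n_spikes_per_train, 0, w)
    while (any(duplicated(times))) {
      dup <- duplicated(times)
      times[dup] <- assign_bins[dup] * w + stats::runif(sum(dup), 0, w)
    }
    # clamp float edge cases into the half-open bin
    times <- pmin(times, (assign_bins + 1) * w - 1e-12)
    spike_train(sort(times), duration)
  })
  input_set(trains, design = "B10.5Hz", target_r = NULL,
            report = list(occupied_bins = occupied_bins, bin_ms = bin_ms,
                          n_spikes = n_spikes_per_train))
}
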