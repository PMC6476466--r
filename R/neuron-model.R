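#' Stochastic input-to-output neuron model
#'
#' A generative stand-in for a patched neuron driven by afferent
#' stimulation: each input pulse is transmitted with probability `p_spike`
#' (optionally attenuated by short-term depression), an emitted spike is
#' delayed by a Gaussian-jittered latency, and a transmitted pulse may
#' elicit a small burst of extra spikes. Output spike times respect an
#' absolute refractory period and the sweep bounds.
#'
#' @param p_spike Per-pulse probability of at least one output spike
#'   (default 0.5, the targeted mid-range transmission probability;
#'   plausible range roughly 0.2-0.8).
#' @param latency_ms Mean response latency after a pulse, ms.
#' @param jitter_ms SD of the Gaussian latency jitter, ms.
#' @param p_burst Probability that a transmitted pulse elicits more than
#'   one spike.
#' @param burst_geom_p Success parameter of the geometric distribution of
#'   extra spikes per burst (extra count = 1 + Geom(`burst_geom_p`)).
#' @param intra_burst_isi_ms Interval between successive spikes in a burst.
#' @param refractory_ms Absolute refractory period, ms (> 0).
#' @param depression Per-transmission release attenuation in (0, 1); 0
#'   disables short-term depression.
#' @param depression_tau_ms Recovery time constant of depression, ms.
#' @return An object of class `"neuron_model"`.
#' @export
neuron_model <- function(p_spike = 0.5, latency_ms = 5, jitter_ms = 2,
                         p_burst = 0.05, burst_geom_p = 0.7,
                         intra_burst_isi_ms = 4, refractory_ms = 2,
                         depression = 0, depression_tau_ms = 200) {
  if (p_spike < 0 || p_spike > 1) stop("'p_spike' must be in [0, 1]",
                                       call. = FALSE)
  if (p_burst < 0 || p_burst > 1) stop("'p_burst' must be in [0, 1]",
                                       call. = FALSE)
  if (refractory_ms <= 0) stop("'refractory_ms' must be > 0", call. = FALSE)
  if (depression < 0 || depression >= 1) stop("'depression' must be in [0, 1)",
                                              call. = FALSE)
  structure(list(p_spike = p_spike, latency_ms = latency_ms,
                 jitter_ms = jitter_ms, p_burst = p_burst,
                 burst_geom_p = burst_geom_p,
                 intra_burst_isi_ms = intra_burst_isi_ms,
                 refractory_ms = refractory_ms, depression = depression,
                 depression_tau_ms = depression_tau_ms),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf(
    "<neuron_model: p_spike %.2f, latency %g±%g ms, p_burst %.2f>\n",
    x$p_spike, x$latency_ms, x$jitter_ms, x$p_burst))
  invisible(x)
}

#' Cell-type presets for the neuron model
#'
#' Qualitative parameterizations of the neuron model per recorded cell
#' type: granule cells (`"GC"`) are sparse, near-Poisson responders; fast
#' spiking interneurons (`"FS"`) transmit reliably and fire bursts; hilar
#' mossy cells (`"HMC"`) are intermediate; CA3 pyramidal cells (`"CA3"`)
#' are sparse but temporally clustered; `"GC+gzn"` is a granule cell under
#' partial disinhibition, with higher transmission and burst probability
#' than `"GC"`. Presets are qualitative: they reproduce orderings (FS
#' burstiest, GC sparsest and least bursty, GC+gzn above GC), not any
#' recorded cell's numbers.
#'
#' @param name One of `"GC"`, `"FS"`, `"HMC"`, `"CA3"`, `"GC+gzn"`.
#' @return A [neuron_model()].
#' @examples
#' celltype_preset("GC")
#' @export
celltype_preset <- function(name = c("GC", "FS", "HMC", "CA3", "GC+gzn")) {
  name <- match.arg(name)
  switch(name,
    "GC"     = neuron_model(p_spike = 0.5,  p_burst = 0.03,
                            burst_geom_p = 0.8, depression = 0.1),
    "FS"     = neuron_model(p_spike = 0.85, p_burst = 0.45,
                            burst_geom_p = 0.45, jitter_ms = 1,
                            intra_burst_isi_ms = 3),
    "HMC"    = neuron_model(p_spike = 0.6,  p_burst = 0.25,
                            burst_geom_p = 0.6),
    "CA3"    = neuron_model(p_spike = 0.4,  p_burst = 0.2,
                            burst_geom_p = 0.6, jitter_ms = 3),
    "GC+gzn" = neuron_model(p_spike = 0.65, p_burst = 0.12,
                            burst_geom_p = 0.7, depression = 0.1))
}

#' Simulate one output sweep
#'
#' Applies the stochastic neuron model to one input pulse train. For each
#' pulse, transmission succeeds with probability `p_spike` times the
#' current depression state; a success emits a spike at
#' `pulse + latency + N(0, jitter)` and, with probability `p_burst`,
#' `1 + Geom(burst_geom_p)` extra spikes at the intra-burst interval.
#' Spikes violating the refractory period or falling outside the sweep are
#' dropped.
#'
#' @param input_train A [spike_train()] of stimulation pulse times.
#' @param model A [neuron_model()].
#' @return A [spike_train()]; possibly empty.
#' @export
simulate_sweep <- function(input_train, model) {
  stopifnot(inherits(input_train, "spike_train"),
            inherits(model, "neuron_model"))
  duration <- input_train$duration
  pulses <- input_train$times
  lat <- model$latency_ms / 1000
  jit <- model$jitter_ms / 1000
  ibi <- model$intra_burst_isi_ms / 1000
  refr <- model$refractory_ms / 1000
  tau_d <- model$depression_tau_ms / 1000
  out <- numeric(0)
  d_state <- 1
  last_pulse <- -Inf
  for (tp in pulses) {
    if (model$depression > 0 && is.finite(last_pulse)) {
      d_state <- 1 - (1 - d_state) * exp(-(tp - last_pulse) / tau_d)
    }
    if (stats::runif(1L) < model$p_spike * d_state) {
      t0 <- tp + lat + if (jit > 0) stats::rnorm(1L, 0, jit) else 0
      spikes <- t0
      if (model$p_burst > 0 && stats::runif(1L) < model$p_burst) {
        k <- 1L + stats::rgeom(1L, model$burst_geom_p)
        spikes <- c(spikes, t0 + seq_len(k) * ibi)
      }
      out <- c(out, spikes)
      if (model$depression > 0) d_state <- d_state * (1 - model$depression)
    }
    last_pulse <- tp
  }
  out <- sort(out[out >= 0 & out < duration])
  if (length(out) > 1L) {
    keep <- c(TRUE, diff(out) >= refr)
    # refractoriness is relative to the last *kept* spike
    while (!all(keep)) {
      out <- out[keep]
      if (length(out) <= 1L) break
      keep <- c(TRUE, diff(out) >= refr)
    }
  }
  spike_train(out, duration)
}

#' Simulate a full recording set
#'
#' Runs [simulate_sweep()] for every train of an input set, `repeats`
#' times, mirroring the stimulation protocol: within each repeat the trains
#' are delivered in order (interleaved), so sweep `k` of repeat `r` is a
#' child of train `k`.
#'
#' @param input An [input_set()].
#' @param model A [neuron_model()].
#' @param repeats Number of repeats; `repeats * n_trains` must equal 50
#'   unless `allow_other_total = TRUE`.
#' @param celltype,condition Labels stored on the recording set.
#' @param allow_other_total Permit non-standard sweep totals (testing).
#' @return A [recording_set()].
#' @export
simulate_recording_set <- function(input, model,
                                   repeats = 50L %/% length(input$trains),
                                   celltype = NA_character_,
                                   condition = NA_character_,
                                   allow_other_total = FALSE) {
  stopifnot(inherits(input, "input_set"))
  n_tr <- length(input$trains)
  if (!allow_other_total && repeats * n_tr != 50L) {
    stop("repeats x n_trains must equal 50 for a standard recording set",
         call. = FALSE)
  }
  sweeps <- vector("list", repeats * n_tr)
  parent_of <- integer(repeats * n_tr)
  k <- 0L
  for (r in seq_len(repeats)) {
    for (i in seq_len(n_tr)) {
      k <- k + 1L
      sweeps[[k]] <- simulate_sweep(input$trains[[i]], model)
      parent_of[k] <- i
    }
  }
  recording_set(input, sweeps, parent_of, celltype = celltype,
                condition = condition, allow_other_total = allow_other_total)
}

#' Per-pulse transmission and burst statistics
#'
#' Empirical per-pulse response statistics of a recording set against its
#' parent trains: for every inter-pulse interval `(pulse_i, pulse_{i+1}]`
#' (the last interval extends to the sweep end), counts output spikes.
#' `p_response` is the fraction of intervals with at least one spike;
#' `p_burst` the fraction with more than one (the burst probability).
#'
#' @param rec A [recording_set()].
#' @return A list with `p_response`, `p_burst` and `n_intervals`.
#' @export
pulse_response_stats <- function(rec) {
  stopifnot(inherits(rec, "recording_set"))
  n_resp <- 0L; n_burst <- 0L; n_int <- 0L
  for (k in seq_along(rec$sweeps)) {
    parent <- rec$input$trains[[rec$parent_of[k]]]
    pulses <- parent$times
    if (!length(pulses)) next
    edges <- c(pulses, parent$duration)
    idx <- findInterval(rec$sweeps[[k]]$times, edges, left.open = TRUE)
    counts <- tabulate(idx[idx >= 1L & idx <= length(pulses)],
                       nbins = length(pulses))
    n_int <- n_int + length(counts)
    n_resp <- n_resp + sum(counts >= 1L)
    n_burst <- n_burst + sum(counts >= 2L)
  }
  list(p_response = n_resp / n_int, p_burst = n_burst / n_int,
       n_intervals = n_int)
}
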