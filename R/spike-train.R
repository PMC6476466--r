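#' Construct a spike train
#'
#' A spike train is a strictly increasing vector of spike times (seconds)
#' on a sweep of fixed duration. Sweeps during which no spikes occurred are
#' valid objects but are flagged empty and excluded from all similarity and
#' feature averages downstream.
#'
#' @param times Numeric vector of spike times in seconds; must be strictly
#'   increasing, with `0 <= t < duration`. May be empty.
#' @param duration Sweep length in seconds (default 2, the standard sweep).
#' @return An object of class `"spike_train"` with elements `times` and
#'   `duration`.
#' @examples
#' st <- spike_train(c(0.005, 0.014, 1.999))
#' n_spikes(st)
#' @export
spike_train <- function(times = numeric(0), duration = 2) {
  times <- as.numeric(times)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("'duration' must be a single positive number (seconds)", call. = FALSE)
  }
  if (length(times)) {
    if (anyNA(times)) stop("spike times must not contain NA", call. = FALSE)
    if (any(times < 0) || any(times >= duration)) {
      bad <- which(times < 0 | times >= duration)[1L]
      stop(sprintf("spike time %g (index %d) outside [0, %g)",
                   times[bad], bad, duration), call. = FALSE)
    }
    if (is.unsorted(times, strictly = TRUE)) {
      stop("spike times must be strictly increasing (no duplicates)",
           call. = FALSE)
    }
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
is_empty_train <- function(x) length(x$times) == 0L

#' @rdname spike_train
#' @export
n_spikes <- function(x) length(x$times)

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes over %g s (%.3g Hz)>\n",
              n_spikes(x), x$duration,
              if (n_spikes(x)) n_spikes(x) / x$duration else 0))
  invisible(x)
}

#' Bin a spike train into a spike-count vector
#'
#' Divides the sweep into time bins of width `tau_w_ms` and counts spikes
#' per bin. Bins are half-open, `[k*tau_w, (k+1)*tau_w)`, so every spike
#' falls in exactly one bin and the total count is conserved. When the bin
#' width does not divide the sweep duration the final, partial bin is kept.
#'
#' @param train A [spike_train()].
#' @param tau_w_ms Bin width in milliseconds (the time scale `tau_w`).
#' @return Integer vector of counts with attributes `tau_w_ms` and
#'   `duration`.
#' @examples
#' bin_train(spike_train(c(0.005, 0.014, 1.999)), tau_w_ms = 10)[c(1, 2, 200)]
#' @export
bin_train <- function(train, tau_w_ms) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(tau_w_ms) || length(tau_w_ms) != 1L || !is.finite(tau_w_ms) ||
      tau_w_ms <= 0) {
    stop("'tau_w_ms' must be a single positive bin width in ms", call. = FALSE)
  }
  w <- tau_w_ms / 1000
  n_bins <- ceiling(train$duration / w - 1e-12)
  idx <- floor(train$times / w) + 1L
  # guard against floating-point edge landing one past the end
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  structure(as.integer(counts), tau_w_ms = tau_w_ms, duration = train$duration)
}

#' Canonical binning time scales
#'
#' The set of bin widths (ms) used throughout the multi-time-scale analysis;
#' each divides the default 2-s sweep exactly.
#' @export
canonical_tau_w <- function() c(5, 10, 20, 50, 100, 250, 500, 1000)

#' Construct an input set
#'
#' An input set is the ensemble of 5 or 10 designed stimulus spike trains
#' delivered repeatedly to the afferents of a recorded (here: simulated)
#' neuron.
#'
#' @param trains List of [spike_train()] objects sharing one duration.
#' @param design Design label: `"P10Hz"`, `"P30Hz"`, `"PdFR"` (Poisson with
#'   varying rate) or `"B10.5Hz"` (fixed-rate bursty).
#' @param target_r Target mean pairwise Pearson correlation at 10 ms, or
#'   `NULL` when the design does not constrain it.
#' @param seed RNG seed recorded for provenance, or `NULL`.
#' @param report Optional generation report (achieved correlation etc.).
#' @return An object of class `"input_set"`.
#' @export
input_set <- function(trains, design = c("P10Hz", "P30Hz", "PdFR", "B10.5Hz"),
                      target_r = NULL, seed = NULL, report = NULL) {
  design <- match.arg(design)
  if (!is.list(trains) || !all(vapply(trains, inherits, TRUE, "spike_train"))) {
    stop("'trains' must be a list of spike_train objects", call. = FALSE)
  }
  if (!length(trains) %in% c(5L, 10L)) {
    stop("an input set has 5 or 10 trains", call. = FALSE)
  }
  durs <- vapply(trains, function(t) t$duration, 0)
  if (length(unique(durs)) != 1L) {
    stop("all trains in a set must share one duration", call. = FALSE)
  }
  if (!is.null(target_r) &&
      (target_r < 0 || target_r > 1)) {
    stop("'target_r' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(trains = trains, design = design, target_r = target_r,
                 seed = seed, report = report),
            class = "input_set")
}

#' @export
print.input_set <- function(x, ...) {
  cat(sprintf("<input_set: design %s, %d trains, duration %g s%s>\n",
              x$design, length(x$trains), x$trains[[1]]$duration,
              if (!is.null(x$target_r))
                sprintf(", target R %.2f", x$target_r) else ""))
  invisible(x)
}

#' Construct a recording set
#'
#' A recording set pairs an input set with the output sweeps it evoked:
#' `repeats x n_trains` child sweeps (50 in the standard protocol), each
#' attributed to exactly one parent input train. Sweeps are ordered as in
#' the stimulation protocol: trains interleaved within each repeat.
#'
#' @param input An [input_set()].
#' @param sweeps List of output [spike_train()] objects.
#' @param parent_of Integer vector, one entry per sweep, giving the index of
#'   the parent input train.
#' @param celltype,condition Optional labels.
#' @param allow_other_total Permit totals other than 50 sweeps (testing).
#' @return An object of class `"recording_set"`.
#' @export
recording_set <- function(input, sweeps, parent_of,
                          celltype = NA_character_, condition = NA_character_,
                          allow_other_total = FALSE) {
  stopifnot(inherits(input, "input_set"))
  if (!is.list(sweeps) || !all(vapply(sweeps, inherits, TRUE, "spike_train"))) {
    stop("'sweeps' must be a list of spike_train objects", call. = FALSE)
  }
  parent_of <- as.integer(parent_of)
  if (length(parent_of) != length(sweeps)) {
    stop("'parent_of' must name one parent per sweep", call. = FALSE)
  }
  n_tr <- length(input$trains)
  if (any(parent_of < 1L | parent_of > n_tr)) {
    stop("parent indices out of range", call. = FALSE)
  }
  if (!allow_other_total && length(sweeps) != 50L) {
    stop("a standard recording set has exactly 50 sweeps ",
         "(use allow_other_total = TRUE to override)", call. = FALSE)
  }
  if (length(sweeps) %% n_tr != 0L ||
      length(unique(tabulate(parent_of, n_tr))) != 1L) {
    stop("every parent train must have the same number of child sweeps",
         call. = FALSE)
  }
  structure(list(input = input, sweeps = sweeps, parent_of = parent_of,
                 celltype = celltype, condition = condition),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf(
    "<recording_set: %d parents x %d repeats = %d sweeps (%d empty)%s>\n",
    length(x$input$trains),
    length(x$sweeps) / length(x$input$trains), length(x$sweeps),
    sum(vapply(x$sweeps, is_empty_train, TRUE)),
    if (!is.na(x$celltype)) paste0(", ", x$celltype) else ""))
  invisible(x)
}

#' Read and write spike-train sets
#'
#' Plain-CSV interchange for input and recording sets. Columns:
#' `set_id`, `train_id` (parent index), `sweep_id` (blank/NA for parent
#' input trains), `spike_time_s`. A JSON sidecar (`<path>.json`) carries
#' per-set metadata (design, target correlation, seed, duration, celltype,
#' condition). Writing then reading reproduces spike times to 1e-9 s.
#'
#' @param sets A list of [input_set()] / [recording_set()] objects (or a
#'   single one) for `write_trains()`.
#' @param path CSV file path.
#' @return `read_trains()` returns a named list of sets; `write_trains()`
#'   returns `path` invisibly.
#' @export
write_trains <- function(sets, path) {
  if (inherits(sets, "input_set") || inherits(sets, "recording_set")) {
    sets <- list(set1 = sets)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- sprintf("set%d", seq_along(sets))
  }
  rows <- list()
  meta <- list()
  for (sid in names(sets)) {
    s <- sets[[sid]]
    inp <- if (inherits(s, "recording_set")) s$input else s
    for (i in seq_along(inp$trains)) {
      tt <- inp$trains[[i]]$times
      if (length(tt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = sid, train_id = i, sweep_id = NA_integer_,
          spike_time_s = tt)
      }
    }
    meta_s <- list(duration = inp$trains[[1]]$duration, design = inp$design,
                   target_r = inp$target_r, seed = inp$seed,
                   n_trains = length(inp$trains))
    if (inherits(s, "recording_set")) {
      for (k in seq_along(s$sweeps)) {
        tt <- s$sweeps[[k]]$times
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = sid, train_id = s$parent_of[k], sweep_id = k,
          spike_time_s = if (length(tt)) tt else NA_real_)
      }
      meta_s$n_sweeps <- length(s$sweeps)
      meta_s$parent_of <- s$parent_of
      meta_s$celltype <- s$celltype
      meta_s$condition <- s$condition
    }
    meta[[sid]] <- meta_s
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trains
#' @export
read_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "train_id", "sweep_id", "spike_time_s")
  if (!all(need %in% names(df))) {
    stop("spike-train CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  out <- list()
  for (sid in unique(df$set_id)) {
    d <- df[df$set_id == sid, , drop = FALSE]
    m <- meta[[as.character(sid)]]
    duration <- if (!is.null(m$duration)) m$duration else 2
    build <- function(times, where) {
      times <- sort(times[!is.na(times)])
      if (any(duplicated(times))) {
        stop(sprintf("duplicate spike time in %s of set %s", where, sid),
             call. = FALSE)
      }
      if (length(times) && (min(times) < 0 || max(times) >= duration)) {
        stop(sprintf("spike time out of [0, %g) in %s of set %s",
                     duration, where, sid), call. = FALSE)
      }
      spike_train(times, duration)
    }
    parents_d <- d[is.na(d$sweep_id), , drop = FALSE]
    n_trains <- if (!is.null(m$n_trains)) m$n_trains else
      max(d$train_id, na.rm = TRUE)
    trains <- lapply(seq_len(n_trains), function(i) {
      build(parents_d$spike_time_s[parents_d$train_id == i],
            sprintf("parent train %d", i))
    })
    inp <- input_set(trains,
                     design = if (!is.null(m$design)) m$design else "P10Hz",
                     target_r = m$target_r, seed = m$seed)
    sweeps_d <- d[!is.na(d$sweep_id), , drop = FALSE]
    if (nrow(sweeps_d)) {
      ks <- sort(unique(sweeps_d$sweep_id))
      sweeps <- lapply(ks, function(k) {
        build(sweeps_d$spike_time_s[sweeps_d$sweep_id == k],
              sprintf("sweep %d", k))
      })
      parent_of <- vapply(ks, function(k) {
        as.integer(sweeps_d$train_id[sweeps_d$sweep_id == k][1L])
      }, 0L)
      out[[as.character(sid)]] <- recording_set(
        inp, sweeps, parent_of,
        celltype = if (!is.null(m$celltype)) m$celltype else NA_character_,
        condition = if (!is.null(m$condition)) m$condition else NA_character_,
        allow_other_total = TRUE)
    } else {
      out[[as.character(sid)]] <- inp
    }
  }
  out
}
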