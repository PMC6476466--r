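#' Binned spike-train similarity metrics
#'
#' Three similarity measures between spike-count vectors, each assuming a
#' different neural code:
#'
#' * `pearson_r()` — Pearson's correlation coefficient between the two
#'   count vectors (binwise synchrony code, in [-1, 1]). Undefined when
#'   either vector has zero variance; the value is then `NaN` and
#'   `defined` is `FALSE` so the pair can be excluded from averages.
#' * `ndp()` — normalized dot product, the cosine of the angle between the
#'   vectors (orthogonality, in [0, 1] for count vectors).
#' * `sf()` — scaling factor, the smaller vector norm divided by the
#'   larger ((0, 1]); sensitive to firing-rate and burstiness differences,
#'   blind to which bins the counts sit in.
#'
#' @param x,y Count vectors from [bin_train()] (any equal-length numeric
#'   vectors are accepted).
#' @return A list with `value`, `metric` and `defined`.
#' @examples
#' pearson_r(c(2, 0, 1), c(1, 0, 2))$value  # 0.5
#' ndp(c(2, 0, 1), c(1, 0, 2))$value        # 0.8
#' sf(c(1, 1), c(2, 2))$value               # 0.5
#' @export
pearson_r <- function(x, y) {
  check_count_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(value = NaN, metric = "R", defined = FALSE))
  }
  list(value = stats::cor(x, y), metric = "R", defined = TRUE)
}

#' @rdname pearson_r
#' @export
ndp <- function(x, y) {
  check_count_pair(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(list(value = NaN, metric = "NDP", defined = FALSE))
  }
  list(value = sum(x * y) / (nx * ny), metric = "NDP", defined = TRUE)
}

#' @rdname pearson_r
#' @export
sf <- function(x, y) {
  check_count_pair(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(list(value = NaN, metric = "SF", defined = FALSE))
  }
  list(value = min(nx, ny) / max(nx, ny), metric = "SF", defined = TRUE)
}

check_count_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  tw_x <- attr(x, "tau_w_ms"); tw_y <- attr(y, "tau_w_ms")
  if (!is.null(tw_x) && !is.null(tw_y) && tw_x != tw_y) {
    stop("count vectors were binned at different time scales", call. = FALSE)
  }
  invisible(NULL)
}

#' Pairwise similarity between two spike trains
#'
#' Dispatches to the binned metrics (after binning both trains at
#' `tau_w_ms`) or to the binless [spike_similarity()]. Empty trains are not
#' compared: the result is flagged undefined.
#'
#' @param a,b [spike_train()] objects of equal duration.
#' @param metric `"R"`, `"NDP"`, `"SF"` or `"SPIKE"`.
#' @param tau_w_ms Bin width in ms (ignored for `"SPIKE"`).
#' @return A list with `value`, `metric`, `defined` (and `tau_w_ms` for
#'   binned metrics).
#' @export
train_similarity <- function(a, b, metric = c("R", "NDP", "SF", "SPIKE"),
                             tau_w_ms = 10) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (a$duration != b$duration) {
    stop("spike trains must have equal durations", call. = FALSE)
  }
  if (is_empty_train(a) || is_empty_train(b)) {
    return(list(value = NaN, metric = metric, defined = FALSE))
  }
  if (metric == "SPIKE") {
    res <- spike_similarity(a, b)
    return(list(value = res$value, metric = "SPIKE", defined = TRUE))
  }
  out <- switch(metric,
                R   = pearson_r(bin_train(a, tau_w_ms), bin_train(b, tau_w_ms)),
                NDP = ndp(bin_train(a, tau_w_ms), bin_train(b, tau_w_ms)),
                SF  = sf(bin_train(a, tau_w_ms), bin_train(b, tau_w_ms)))
  out$tau_w_ms <- tau_w_ms
  out
}

#' Pairwise similarity matrix over a collection of spike trains
#'
#' Builds the square symmetric matrix of pairwise similarities over a list
#' of spike trains (e.g. the 5 parents plus 50 sweeps of a recording set,
#' giving the 55 x 55 matrix). The diagonal is the self-similarity (1 for
#' every metric). Empty trains are kept in the matrix as `NA` rows/columns
#' and reported in the `excluded` attribute; pairs where Pearson's R is
#' undefined (a zero-variance count vector) are `NaN`.
#'
#' @param trains List of [spike_train()] objects (or a [recording_set()],
#'   in which case parents are rows 1..n and sweeps follow, and the parent
#'   map is attached).
#' @param metric,tau_w_ms As in [train_similarity()].
#' @return A matrix of class `"similarity_matrix"` with attributes
#'   `metric`, `tau_w_ms`, `excluded` (indices of empty trains),
#'   `n_parents` and `parent_of` when built from a recording set.
#' @export
pairwise_matrix <- function(trains, metric = c("R", "NDP", "SF", "SPIKE"),
                            tau_w_ms = 10) {
  metric <- match.arg(metric)
  n_parents <- NA_integer_
  parent_of <- NULL
  if (inherits(trains, "recording_set")) {
    rec <- trains
    n_parents <- length(rec$input$trains)
    parent_of <- rec$parent_of
    trains <- c(rec$input$trains, rec$sweeps)
  }
  n <- length(trains)
  empty <- which(vapply(trains, is_empty_train, TRUE))
  if (n - length(empty) < 2L) {
    stop("need at least two non-empty trains", call. = FALSE)
  }
  binned <- NULL
  if (metric != "SPIKE") {
    binned <- lapply(trains, function(t) {
      if (is_empty_train(t)) NULL else bin_train(t, tau_w_ms)
    })
  }
  m <- matrix(NA_real_, n, n)
  d <- rep(1, n)
  d[empty] <- NA_real_
  diag(m) <- d
  for (i in seq_len(n - 1L)) {
    if (i %in% empty) next
    for (j in seq.int(i + 1L, n)) {
      if (j %in% empty) next
      v <- if (metric == "SPIKE") {
        spike_similarity(trains[[i]], trains[[j]])$value
      } else {
        switch(metric,
               R   = pearson_r(binned[[i]], binned[[j]]),
               NDP = ndp(binned[[i]], binned[[j]]),
               SF  = sf(binned[[i]], binned[[j]]))$value
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, metric = metric,
            tau_w_ms = if (metric == "SPIKE") NA_real_ else tau_w_ms,
            excluded = empty, n_parents = n_parents, parent_of = parent_of,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<%d x %d similarity matrix, metric %s%s; %d excluded>\n",
              nrow(x), ncol(x), attr(x, "metric"),
              if (!is.na(attr(x, "tau_w_ms")))
                sprintf(" at tau_w %g ms", attr(x, "tau_w_ms")) else "",
              length(attr(x, "excluded"))))
  invisible(x)
}
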