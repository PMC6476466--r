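#' Pattern-separation graph points from a similarity matrix
#'
#' The core pairwise bookkeeping: for every pair of parent input trains
#' `(i, j)`, the input similarity `s_input` is read from the input-input
#' block of the matrix and the output similarity `s_output` is the
#' unweighted mean over all child(i) x child(j) sweep pairs (comparisons
#' between sweeps sharing a parent are never used). Undefined pairs (empty
#' sweeps, undefined Pearson R) are dropped from the mean; a parent pair
#' keeps its point while at least one valid child pair remains.
#'
#' @param m A `"similarity_matrix"` built from a [recording_set()] via
#'   [pairwise_matrix()].
#' @return A data frame of class `"separation_points"` with one row per
#'   parent pair: `parent_i`, `parent_j`, `s_input`, `s_output`,
#'   `n_child_pairs` (valid pairs averaged), `n_excluded`. Attributes
#'   `metric` and `tau_w_ms` carry over.
#' @export
separation_points <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  n_parents <- attr(m, "n_parents")
  parent_of <- attr(m, "parent_of")
  if (is.na(n_parents) || is.null(parent_of)) {
    stop("matrix lacks parentage; build it from a recording_set",
         call. = FALSE)
  }
  sweep_rows <- n_parents + seq_along(parent_of)
  pairs <- utils::combn(n_parents, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    rows_i <- sweep_rows[parent_of == i]
    rows_j <- sweep_rows[parent_of == j]
    block <- m[rows_i, rows_j, drop = FALSE]
    vals <- block[is.finite(block)]
    data.frame(parent_i = i, parent_j = j,
               s_input = m[i, j],
               s_output = if (length(vals)) mean(vals) else NA_real_,
               n_child_pairs = length(vals),
               n_excluded = length(block) - length(vals))
  })
  out <- do.call(rbind, res)
  dropped <- out$n_child_pairs == 0L | !is.finite(out$s_input)
  if (any(dropped)) {
    warning(sprintf("%d parent pair(s) dropped: no valid child pairs",
                    sum(dropped)), call. = FALSE)
    out <- out[!dropped, , drop = FALSE]
  }
  structure(out, metric = attr(m, "metric"), tau_w_ms = attr(m, "tau_w_ms"),
            class = c("separation_points", "data.frame"))
}

#' Feature-difference pattern-separation graph
#'
#' Difference-based analogue of [separation_points()]: for every parent
#' pair, the absolute difference of a per-train feature (firing rate,
#' Compactness or Occupancy) between the two parents is compared with the
#' mean absolute difference over all cross-parent sweep pairs. Note the
#' inverted reading relative to similarity graphs: output differences
#' larger than input differences (points above the identity line) indicate
#' pattern separation.
#'
#' @param rec A [recording_set()].
#' @param feature `"firing_rate"`, `"compactness"` or `"occupancy"`.
#' @param tau_w_ms Bin width for the binned features, ms.
#' @return A data frame of class `"separation_points"` with `d_input` /
#'   `d_output` columns (one row per parent pair).
#' @export
feature_separation_points <- function(rec,
                                      feature = c("firing_rate",
                                                  "compactness", "occupancy"),
                                      tau_w_ms = 10) {
  stopifnot(inherits(rec, "recording_set"))
  feature <- match.arg(feature)
  fun <- switch(feature,
                firing_rate = function(t) firing_rate(t),
                compactness = function(t) compactness(t, tau_w_ms),
                occupancy = function(t) occupancy(t, tau_w_ms))
  val_of <- function(t) if (is_empty_train(t)) NA_real_ else fun(t)
  v_in <- vapply(rec$input$trains, val_of, 0)
  v_out <- vapply(rec$sweeps, val_of, 0)
  n_parents <- length(rec$input$trains)
  pairs <- utils::combn(n_parents, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    d_out <- abs(outer(v_out[rec$parent_of == i],
                       v_out[rec$parent_of == j], `-`))
    vals <- d_out[is.finite(d_out)]
    data.frame(parent_i = i, parent_j = j,
               d_input = abs(v_in[i] - v_in[j]),
               d_output = if (length(vals)) mean(vals) else NA_real_,
               n_child_pairs = length(vals),
               n_excluded = length(d_out) - length(vals))
  })
  out <- do.call(rbind, res)
  out <- out[out$n_child_pairs > 0L & is.finite(out$d_input), , drop = FALSE]
  structure(out, metric = feature, tau_w_ms = tau_w_ms,
            class = c("separation_points", "data.frame"))
}

#' Gini mean difference (mean absolute pairwise difference)
#'
#' The dispersion of a feature across the trains of a set: the mean of
#' `|x_i - x_j|` over all allowed pairs. Self-comparisons are never
#' counted; an optional grouping vector excludes pairs sharing a group
#' (used to drop same-parent sweep pairs).
#'
#' @param values Numeric feature values, one per train.
#' @param groups Optional vector of group labels; pairs within one group
#'   are excluded.
#' @return The mean absolute pairwise difference.
#' @examples
#' gini_mean_difference(c(0, 1, 2))  # 4/3
#' @export
gini_mean_difference <- function(values, groups = NULL) {
  ok <- is.finite(values)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(values))
    groups <- groups[ok]
  }
  values <- values[ok]
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  d <- abs(outer(values, values, `-`))
  use <- upper.tri(d)
  if (!is.null(groups)) {
    same <- outer(groups, groups, `==`)
    use <- use & !same
  }
  if (!any(use)) stop("no allowed pairs after exclusions", call. = FALSE)
  mean(d[use])
}

#' Dispersion-based separation summary for one feature
#'
#' Compares the dispersion (Gini mean difference) of a feature across the
#' input trains with the dispersion across the output sweeps (same-parent
#' sweep pairs excluded). The separation level is
#' `dispersion_output - dispersion_input`: positive values indicate
#' pattern separation through variation of that feature, negative values
#' pattern convergence.
#'
#' @param rec A [recording_set()].
#' @param feature,tau_w_ms As in [feature_separation_points()].
#' @return A one-row data frame: `feature`, `tau_w_ms`,
#'   `dispersion_input`, `dispersion_output`, `separation_level`.
#' @export
dispersion_summary <- function(rec,
                               feature = c("firing_rate", "compactness",
                                           "occupancy"),
                               tau_w_ms = 10) {
  stopifnot(inherits(rec, "recording_set"))
  feature <- match.arg(feature)
  fun <- switch(feature,
                firing_rate = function(t) firing_rate(t),
                compactness = function(t) compactness(t, tau_w_ms),
                occupancy = function(t) occupancy(t, tau_w_ms))
  val_of <- function(t) if (is_empty_train(t)) NA_real_ else fun(t)
  v_in <- vapply(rec$input$trains, val_of, 0)
  v_out <- vapply(rec$sweeps, val_of, 0)
  ok <- is.finite(v_out)
  disp_in <- gini_mean_difference(v_in)
  disp_out <- gini_mean_difference(v_out[ok], groups = rec$parent_of[ok])
  data.frame(feature = feature, tau_w_ms = tau_w_ms,
             dispersion_input = disp_in, dispersion_output = disp_out,
             separation_level = disp_out - disp_in)
}

#' Signed distances to the identity line
#'
#' For similarity-based graph points, the signed perpendicular distance of
#' each `(s_input, s_output)` point to the identity line,
#' `d = (s_input - s_output) / sqrt(2)`: positive distances mean the
#' outputs were less similar than the inputs (pattern separation),
#' negative ones pattern convergence. For difference-based points
#' (`d_input` / `d_output` columns) the sign is flipped so that positive
#' still reads as separation.
#'
#' @param points A `"separation_points"` data frame.
#' @return A list with `distances` (one per point), `median`, and the
#'   empirical cumulative distribution function `ecdf`.
#' @export
identity_distance <- function(points) {
  stopifnot(inherits(points, "separation_points"))
  d <- if ("s_input" %in% names(points)) {
    (points$s_input - points$s_output) / sqrt(2)
  } else {
    (points$d_output - points$d_input) / sqrt(2)
  }
  list(distances = d, median = stats::median(d), ecdf = stats::ecdf(d))
}
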