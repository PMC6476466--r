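#' Fit a pattern-separation graph
#'
#' Ordinary least-squares fit of `s_output` on `s_input` (or `d_output` on
#' `d_input`), either linear or parabolic (quadratic in the predictor,
#' unconstrained). Returns the coefficients, R-squared and, for the linear
#' model, 95% confidence intervals on slope and intercept.
#'
#' @param points A `"separation_points"` data frame, or any data frame
#'   with `s_input` / `s_output` (or `d_input` / `d_output`) columns.
#' @param model `"linear"` or `"parabolic"`.
#' @return A list of class `"separation_fit"`: `model`, `coefficients`,
#'   `r_squared`, `conf_int` (linear only) and the underlying `lm` fit.
#' @export
fit_graph <- function(points, model = c("linear", "parabolic")) {
  model <- match.arg(model)
  xy <- graph_xy(points)
  n_min <- if (model == "linear") 3L else 4L
  if (nrow(xy) < n_min) {
    stop(sprintf("need at least %d points for a %s fit", n_min, model),
         call. = FALSE)
  }
  fit <- if (model == "linear") {
    stats::lm(y ~ x, data = xy)
  } else {
    stats::lm(y ~ x + I(x^2), data = xy)
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient fit: predictor values do not span the model",
         call. = FALSE)
  }
  out <- list(model = model,
              coefficients = stats::coef(fit),
              r_squared = summary(fit)$r.squared,
              conf_int = if (model == "linear") stats::confint(fit) else NULL,
              fit = fit)
  class(out) <- "separation_fit"
  out
}

graph_xy <- function(points) {
  if (all(c("s_input", "s_output") %in% names(points))) {
    data.frame(x = points$s_input, y = points$s_output)
  } else if (all(c("d_input", "d_output") %in% names(points))) {
    data.frame(x = points$d_input, y = points$d_output)
  } else {
    stop("points must carry s_input/s_output or d_input/d_output columns",
         call. = FALSE)
  }
}

#' @export
print.separation_fit <- function(x, ...) {
  cat(sprintf("<%s fit: %s; R^2 = %.3f>\n", x$model,
              paste(sprintf("%.3g", x$coefficients), collapse = ", "),
              x$r_squared))
  invisible(x)
}

#' One-sample separation test for one input set
#'
#' Two-tailed one-sample t-test of the paired differences
#' `s_input - s_output` (or `d_output - d_input` for difference-based
#' points, so that positive always reads as separation) against zero.
#' Classifies the input set as `"separation"`, `"convergence"` or
#' `"neither"` at `alpha`. A Kolmogorov-Smirnov normality check of the
#' differences is reported alongside but does not gate the test; set
#' `use_wilcoxon = TRUE` to use a signed-rank test instead.
#'
#' @param points A `"separation_points"` data frame (one input set's
#'   points).
#' @param alpha Significance level (default 0.05).
#' @param use_wilcoxon Use a Wilcoxon signed-rank test instead of the
#'   t-test.
#' @return A list: `p_value`, `statistic`, `mean_difference`, `direction`,
#'   `normality_p`, `method`. If every difference is exactly zero the test
#'   degenerates; `p_value` is `NA` and `direction` `"neither"` with an
#'   `exact_tie` flag.
#' @export
separation_ttest <- function(points, alpha = 0.05, use_wilcoxon = FALSE) {
  xy <- graph_xy(points)
  d <- if ("s_input" %in% names(points)) xy$x - xy$y else xy$y - xy$x
  d <- d[is.finite(d)]
  if (length(d) < 2L) stop("need at least two paired differences",
                           call. = FALSE)
  norm_p <- tryCatch(
    suppressWarnings(stats::ks.test(scale(d), "pnorm")$p.value),
    error = function(e) NA_real_)
  if (stats::sd(d) == 0) {
    return(list(p_value = if (all(d == 0)) NA_real_ else 0,
                statistic = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                mean_difference = mean(d),
                direction = if (all(d == 0)) "neither"
                            else if (d[1] > 0) "separation" else "convergence",
                normality_p = norm_p, method = "exact tie",
                exact_tie = TRUE, n = length(d)))
  }
  tt <- if (use_wilcoxon) {
    suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = "two.sided"))
  } else {
    stats::t.test(d, mu = 0, alternative = "two.sided")
  }
  direction <- if (tt$p.value < alpha) {
    if (mean(d) > 0) "separation" else "convergence"
  } else "neither"
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       mean_difference = mean(d), direction = direction,
       normality_p = norm_p,
       method = if (use_wilcoxon) "wilcoxon" else "t-test",
       exact_tie = FALSE, n = length(d))
}

#' Separate-lines ANCOVA across groups
#'
#' Compares pattern-separation graphs between experimental groups
#' (treatments or cell types): a separate-lines linear model
#' `s_output ~ s_input * group` with the input similarity as continuous
#' predictor and the group as categorical predictor. Reports the overall
#' group and interaction (slope-difference) tests and pairwise
#' slope/intercept contrasts with Tukey adjustment (a plain contrast when
#' there are only two groups).
#'
#' @param points A `"separation_points"`-style data frame pooled over
#'   groups.
#' @param group Factor (or coercible) of group labels, one per row.
#' @return A list of class `"ancova_groups"`: `anova_table`, `p_group`,
#'   `p_interaction`, `slopes` (per-group slope estimates with contrasts),
#'   `intercepts`, and the underlying `lm` fit.
#' @export
ancova_groups <- function(points, group) {
  xy <- graph_xy(points)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(group) < 3L)) {
    stop("each group needs at least three points", call. = FALSE)
  }
  dat <- data.frame(x = xy$x, y = xy$y, g = group)
  fit <- stats::lm(y ~ x * g, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design in ANCOVA", call. = FALSE)
  }
  an <- stats::anova(fit)
  slopes <- emmeans::emtrends(fit, ~ g, var = "x")
  slope_contrasts <- summary(emmeans::contrast(slopes, method = "pairwise",
                                               adjust = "tukey"))
  # intercepts compared at x = 0 on purpose (separate-lines model)
  means <- suppressMessages(emmeans::emmeans(fit, ~ g, at = list(x = 0)))
  intercept_contrasts <- summary(emmeans::contrast(means,
                                                   method = "pairwise",
                                                   adjust = "tukey"))
  out <- list(anova_table = an,
              p_group = an["g", "Pr(>F)"],
              p_interaction = an["x:g", "Pr(>F)"],
              slopes = summary(slopes),
              slope_contrasts = slope_contrasts,
              intercepts = summary(means),
              intercept_contrasts = intercept_contrasts,
              fit = fit)
  class(out) <- "ancova_groups"
  out
}

#' @export
print.ancova_groups <- function(x, ...) {
  cat(sprintf("<ANCOVA: group p = %.3g, interaction p = %.3g>\n",
              x$p_group, x$p_interaction))
  invisible(x)
}

#' Machine-readable analysis report
#'
#' Collates per-metric, per-time-scale separation results for a batch of
#' recording sets into a reproducible report: graph points, linear fits,
#' one-sample separation tests per input set, exclusion counts, and the
#' configuration (seed, metrics, time scales). Two runs with identical
#' seeds and configuration produce byte-identical JSON.
#'
#' @param recordings Named list of [recording_set()] objects.
#' @param metrics Similarity metrics to analyze.
#' @param tau_w_ms Time scales, ms (ignored for `"SPIKE"`).
#' @param seed Seed recorded for provenance.
#' @param path Optional path; when given the JSON is written there.
#' @return The report as a list (invisibly when written to `path`).
#' @export
separation_report <- function(recordings, metrics = c("R", "NDP", "SF"),
                              tau_w_ms = 10, seed = NULL, path = NULL) {
  if (is.null(names(recordings))) {
    names(recordings) <- sprintf("rec%d", seq_along(recordings))
  }
  entries <- list()
  for (metric in metrics) {
    scales <- if (metric == "SPIKE") NA_real_ else tau_w_ms
    for (tw in scales) {
      pts_all <- list()
      tests <- list()
      excl <- 0L
      for (nm in names(recordings)) {
        rec <- recordings[[nm]]
        m <- pairwise_matrix(rec, metric = metric,
                             tau_w_ms = if (is.na(tw)) 10 else tw)
        pts <- suppressWarnings(separation_points(m))
        excl <- excl + sum(pts$n_excluded) +
          length(attr(m, "excluded"))
        pts$set <- nm
        pts_all[[nm]] <- pts
        tests[[nm]] <- separation_ttest(pts)[
          c("p_value", "mean_difference", "direction", "n")]
      }
      pts_df <- do.call(rbind, pts_all)
      fit <- tryCatch(fit_graph(pts_df, "linear"), error = function(e) NULL)
      entries[[length(entries) + 1L]] <- list(
        metric = metric, tau_w_ms = tw,
        n_points = nrow(pts_df),
        points = pts_df[, c("set", "parent_i", "parent_j", "s_input",
                            "s_output", "n_child_pairs")],
        linear_fit = if (!is.null(fit)) {
          list(coefficients = as.list(fit$coefficients),
               r_squared = fit$r_squared)
        },
        tests = tests,
        n_excluded_pairs = excl)
    }
  }
  report <- list(config = list(seed = seed, metrics = metrics,
                               tau_w_ms = tau_w_ms,
                               n_recordings = length(recordings)),
                 results = entries)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 12,
                         dataframe = "columns", null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}
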