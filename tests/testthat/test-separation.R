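pass_through_model <- function() {
  neuron_model(p_spike = 1, latency_ms = 0, jitter_ms = 0, p_burst = 0,
               refractory_ms = 1e-9)
}

test_that("pair bookkeeping matches the closed-form combinatorics", {
  set.seed(111)
  for (cfg in list(c(n = 5L, r = 10L), c(n = 10L, r = 5L))) {
    n <- cfg[["n"]]; r <- cfg[["r"]]
    inp <- if (n == 5) gen_correlated_set(0.48) else gen_varying_rate_set()
    rec <- simulate_recording_set(inp, celltype_preset("GC"), repeats = r)
    m <- pairwise_matrix(rec, "NDP", 10)
    expect_identical(dim(m), c(n + 50L, n + 50L))
    pts <- separation_points(m)
    expect_identical(nrow(pts), as.integer(n * (n - 1) / 2))
    # every point averages r^2 child pairs (minus any excluded)
    expect_true(all(pts$n_child_pairs + pts$n_excluded == r^2))
    # same-parent exclusions: n * r(r-1)/2 pairs never enter any point
    total_output_pairs <- choose(50, 2)
    cross_parent_pairs <- n * (n - 1) / 2 * r^2
    same_parent_pairs <- n * r * (r - 1) / 2
    expect_identical(total_output_pairs,
                     cross_parent_pairs + same_parent_pairs)
  }
})

test_that("a deterministic pass-through gives no false separation", {
  set.seed(112)
  inp <- gen_correlated_set(0.76)
  rec <- simulate_recording_set(inp, pass_through_model())
  for (metric in c("R", "NDP", "SF", "SPIKE")) {
    for (tw in c(10, 250)) {
      m <- pairwise_matrix(rec, metric, tw)
      pts <- separation_points(m)
      expect_equal(pts$s_output, pts$s_input, tolerance = 1e-12)
      if (metric == "SPIKE") break  # binless: one scale only
    }
  }
  # and for feature-difference graphs
  for (feat in c("firing_rate", "compactness", "occupancy")) {
    pts <- feature_separation_points(rec, feat, 10)
    expect_equal(pts$d_output, pts$d_input, tolerance = 1e-12)
  }
})

test_that("empty sweeps are excluded pairwise, points survive", {
  set.seed(113)
  inp <- gen_correlated_set(0.48)
  rec <- simulate_recording_set(inp, pass_through_model())
  # silence two sweeps of parent 1
  kids <- which(rec$parent_of == 1)[1:2]
  for (k in kids) rec$sweeps[[k]] <- spike_train(numeric(0), 2)
  m <- pairwise_matrix(rec, "R", 10)
  expect_identical(attr(m, "excluded"), 5L + kids)
  pts <- separation_points(m)
  expect_identical(nrow(pts), 10L)
  involving1 <- pts$parent_i == 1 | pts$parent_j == 1
  expect_true(all(pts$n_child_pairs[involving1] == 80L))  # 8 x 10
  expect_true(all(pts$n_child_pairs[!involving1] == 100L))
})

test_that("feature separation points carry the right input abscissa", {
  set.seed(114)
  inp <- gen_varying_rate_set()
  rec <- simulate_recording_set(inp, pass_through_model(), repeats = 5)
  pts <- feature_separation_points(rec, "firing_rate")
  expect_identical(nrow(pts), 45L)
  fr <- vapply(inp$trains, firing_rate, 0)
  extreme <- pts[pts$parent_i == 1 & pts$parent_j == 10, ]
  expect_equal(extreme$d_input, abs(fr[1] - fr[10]))
})

test_that("a rate-clamped neuron converges firing-rate differences", {
  set.seed(115)
  inp <- gen_varying_rate_set()
  # transmission scaled so every output sits near one rate regardless of
  # the input rate: strong convergence through the firing-rate code
  sweeps <- list(); parent_of <- integer(0)
  for (r in 1:5) {
    for (i in 1:10) {
      target_rate <- 8
      keep_p <- min(1, target_rate / firing_rate(inp$trains[[i]]))
      tt <- inp$trains[[i]]$times
      tt <- tt[stats::runif(length(tt)) < keep_p]
      sweeps[[length(sweeps) + 1L]] <- spike_train(tt, 2)
      parent_of <- c(parent_of, i)
    }
  }
  rec <- recording_set(inp, sweeps, parent_of)
  pts <- feature_separation_points(rec, "firing_rate")
  expect_lt(mean(pts$d_output), mean(pts$d_input))
})

test_that("Gini mean difference: worked values and exclusions", {
  expect_equal(gini_mean_difference(c(0, 1, 2)), 4 / 3)
  expect_equal(gini_mean_difference(rep(3.7, 10)), 0)
  expect_error(gini_mean_difference(1), "at least two")
  # grouped exclusion drops within-group pairs
  v <- c(1, 2, 10, 20)
  g <- c("a", "a", "b", "b")
  expect_equal(gini_mean_difference(v, g), mean(c(9, 19, 8, 18)))
  expect_error(gini_mean_difference(c(1, 2), c("a", "a")), "no allowed pairs")
})

test_that("dispersion summary signs separation vs convergence", {
  set.seed(116)
  b <- gen_bursty_set()
  rec <- simulate_recording_set(b, pass_through_model(), repeats = 5)
  d <- dispersion_summary(rec, "occupancy", 10)
  expect_equal(d$separation_level, 0, tolerance = 1e-12)
  # input set B occupancy dispersion is over 45 pairs; value from the
  # exact occupied-bin design: mean |21/k_i - 21/k_j|
  occ <- 21 / seq(3, 21, by = 2)
  expect_equal(d$dispersion_input, gini_mean_difference(occ))
})

test_that("identity distances follow the point-line formula and signs", {
  pts <- structure(
    data.frame(parent_i = 1:3, parent_j = 2:4,
               s_input = c(0.76, 0.76, 0.3),
               s_output = c(0.76, 0.30, 0.5),
               n_child_pairs = 100L, n_excluded = 0L),
    metric = "R", tau_w_ms = 10,
    class = c("separation_points", "data.frame"))
  id <- identity_distance(pts)
  expect_equal(id$distances[1], 0)
  expect_equal(id$distances[2], 0.46 / sqrt(2))
  expect_lt(id$distances[3], 0)  # above the line: convergence
  expect_equal(id$median, stats::median(id$distances))
  expect_equal(id$ecdf(0.46 / sqrt(2)), 1)
})
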