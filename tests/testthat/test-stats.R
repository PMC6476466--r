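make_points <- function(x, y) {
  structure(data.frame(parent_i = seq_along(x), parent_j = seq_along(x) + 1L,
                       s_input = x, s_output = y,
                       n_child_pairs = 100L, n_excluded = 0L),
            metric = "R", tau_w_ms = 10,
            class = c("separation_points", "data.frame"))
}

test_that("fits recover exact generating models", {
  x <- seq(0, 1, length.out = 10)
  # noise-free points: lm warns about the perfect fit, which is the point
  f1 <- suppressWarnings(fit_graph(make_points(x, 0.5 * x + 0.1), "linear"))
  expect_equal(unname(f1$coefficients), c(0.1, 0.5), tolerance = 1e-10)
  expect_equal(f1$r_squared, 1, tolerance = 1e-10)
  expect_true(f1$conf_int["x", 1] <= 0.5 && 0.5 <= f1$conf_int["x", 2])

  f2 <- suppressWarnings(fit_graph(make_points(x, x^2), "parabolic"))
  expect_equal(unname(f2$coefficients), c(0, 0, 1), tolerance = 1e-8)

  expect_error(fit_graph(make_points(x[1:2], x[1:2]), "linear"), "at least 3")
  expect_error(fit_graph(make_points(rep(0.5, 5), rnorm(5)), "linear"),
               "rank-deficient")
})

test_that("linear-fit confidence interval covers the generating slope", {
  set.seed(121)
  x <- seq(0.1, 1, length.out = 20)
  covered <- mean(replicate(200, {
    f <- fit_graph(make_points(x, 0.6 * x + 0.05 +
                                 stats::rnorm(20, 0, 0.05)), "linear")
    f$conf_int["x", 1] <= 0.6 && 0.6 <= f$conf_int["x", 2]
  }))
  expect_gte(covered, 0.90)
})

test_that("separation t-test: trivial directions and exact ties", {
  x <- seq(0.2, 0.9, length.out = 10)
  tt0 <- separation_ttest(make_points(x, x))
  expect_true(tt0$exact_tie)
  expect_identical(tt0$direction, "neither")

  set.seed(122)
  tt_sep <- separation_ttest(make_points(x, x - 0.2 +
                                           stats::rnorm(10, 0, 1e-3)))
  expect_identical(tt_sep$direction, "separation")
  expect_lt(tt_sep$p_value, 1e-6)

  tt_conv <- separation_ttest(make_points(x, x + 0.2 +
                                            stats::rnorm(10, 0, 1e-3)))
  expect_identical(tt_conv$direction, "convergence")

  # difference-based points read the opposite way
  dpts <- structure(data.frame(d_input = x, d_output = x + 0.2 +
                                 stats::rnorm(10, 0, 1e-3)),
                    class = c("separation_points", "data.frame"))
  expect_identical(separation_ttest(dpts)$direction, "separation")
})

test_that("separation t-test holds its type-I error under a null", {
  set.seed(123)
  x <- seq(0.2, 0.9, length.out = 10)
  fp <- mean(replicate(1000, {
    y <- x + stats::rnorm(10, 0, 0.05)  # symmetric noise: no separation
    separation_ttest(make_points(x, y))$p_value < 0.05
  }))
  expect_equal(fp, 0.05, tolerance = 0.4)  # ~0.03-0.07 over 1000 draws
})

test_that("ANCOVA: identical groups are null, distinct slopes are found", {
  set.seed(124)
  x <- rep(seq(0.1, 1, length.out = 35), 2)
  y0 <- 0.5 * x + 0.1
  pts <- make_points(c(x, x), c(y0, y0) + stats::rnorm(140, 0, 0.05))
  g <- rep(c("a", "b"), each = 140 / 2)
  a0 <- ancova_groups(pts, g)
  expect_gt(a0$p_interaction, 0.05)

  # slopes 0.2 vs 0.8, n = 70 per group, sd 0.05: interaction detected
  hits <- mean(replicate(50, {
    y <- c(0.2 * x + 0.1, 0.8 * x + 0.1) + stats::rnorm(140, 0, 0.05)
    ancova_groups(make_points(c(x, x), y), g)$p_interaction < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("ANCOVA permutation null keeps the interaction rate near alpha", {
  set.seed(125)
  x <- rep(seq(0.1, 1, length.out = 30), 2)
  y <- 0.5 * x + 0.1 + stats::rnorm(60, 0, 0.05)
  pts <- make_points(x, y)
  rate <- mean(replicate(200, {
    g <- sample(rep(c("a", "b"), each = 30))
    ancova_groups(pts, g)$p_interaction < 0.05
  }))
  expect_lt(abs(rate - 0.05), 0.06)
})

test_that("ANCOVA reports per-group slopes with Tukey-adjusted contrasts", {
  set.seed(126)
  x <- seq(0.1, 1, length.out = 40)
  y <- c(0.2 * x, 0.5 * x, 0.8 * x) + stats::rnorm(120, 0, 0.03)
  pts <- make_points(rep(x, 3), y)
  g <- rep(c("a", "b", "c"), each = 40)
  res <- ancova_groups(pts, g)
  expect_identical(nrow(res$slopes), 3L)
  expect_equal(res$slopes$x.trend, c(0.2, 0.5, 0.8), tolerance = 0.2)
  expect_identical(nrow(res$slope_contrasts), 3L)  # 3 pairwise contrasts
  expect_error(ancova_groups(pts, rep("a", 120)), "two groups")
})

test_that("reports are byte-identical under identical seed and config", {
  run_once <- function() {
    set.seed(127)
    inp <- gen_correlated_set(0.76)
    recs <- list(r1 = simulate_recording_set(inp, celltype_preset("GC")),
                 r2 = simulate_recording_set(inp, celltype_preset("GC")))
    path <- tempfile(fileext = ".json")
    separation_report(recs, metrics = c("R", "NDP"), tau_w_ms = c(10, 100),
                      seed = 127, path = path)
    readLines(path)
  }
  expect_identical(run_once(), run_once())
})

test_that("report counts points and exclusions across a set battery", {
  set.seed(128)
  recs <- lapply(1:3, function(i) {
    simulate_recording_set(gen_correlated_set(0.5), celltype_preset("GC"))
  })
  names(recs) <- sprintf("rec%d", 1:3)
  rep_out <- separation_report(recs, metrics = "R", tau_w_ms = 10, seed = 1)
  entry <- rep_out$results[[1]]
  expect_identical(entry$n_points, 30L)  # 3 sets x 10 parent pairs
  expect_identical(length(entry$tests), 3L)
  expect_true(all(c("p_value", "direction") %in% names(entry$tests$rec1)))
})
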