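test_that("firing rate is count over duration", {
  expect_equal(firing_rate(spike_train(seq(0.1, 1.9, length.out = 21))), 10.5)
  expect_equal(firing_rate(spike_train(1.0)), 0.5)
  expect_equal(firing_rate(spike_train(seq(0.01, 1.99, length.out = 60))), 30)
  expect_error(firing_rate(spike_train()), "empty")
})

test_that("compactness worked values at tau_w = 10 ms (N = 200)", {
  # all spikes in one bin: the maximum 1 - 1/N
  clustered <- spike_train(seq(0.5001, 0.5099, length.out = 21))
  expect_equal(compactness(clustered, 10), 1 - 1 / 200)
  expect_equal(compactness(clustered, 10), 0.995)
  # 21 spikes in 21 distinct bins
  spread <- spike_train(seq(0.005, 1.905, by = 0.095))
  expect_identical(n_spikes(spread), 21L)
  expect_equal(compactness(spread, 10), 1 - 21 / 200)
  # every bin occupied -> 0
  dense <- spike_train(seq(0.0005, 1.9995, by = 0.001))
  expect_equal(compactness(dense, 1), 0)
  expect_error(compactness(spike_train(), 10), "empty")
})

test_that("occupancy worked values and lower bound", {
  # 21 spikes in 7 bins of 10 ms -> exactly 3 spikes per occupied bin
  times <- as.vector(outer(c(0.001, 0.004, 0.007),
                           seq(0, 0.06, by = 0.01)[1:7], `+`))
  st <- spike_train(sort(times))
  expect_equal(occupancy(st, 10), 3)
  # all spikes in distinct bins -> 1 (the lower bound)
  expect_equal(occupancy(spike_train(seq(0.005, 1.905, by = 0.095)), 10), 1)
  expect_equal(occupancy(spike_train(0.3), 10), 1)
})

test_that("occupancy at the full-sweep scale equals the spike count", {
  set.seed(101)
  for (i in 1:10) {
    st <- gen_poisson_train(stats::runif(1, 3, 30))
    if (is_empty_train(st)) next
    expect_equal(occupancy(st, 2000), n_spikes(st))
    expect_equal(occupancy(st, 2000), 2 * firing_rate(st))
  }
})

test_that("compactness and occupancy are monotonically related at fixed count", {
  set.seed(102)
  b <- gen_bursty_set()
  comp <- vapply(b$trains, compactness, 0, tau_w_ms = 10)
  occ <- vapply(b$trains, occupancy, 0, tau_w_ms = 10)
  # same spike count everywhere: fewer occupied bins raises both together
  expect_identical(order(comp), order(occ))
  expect_equal(stats::cor(comp, occ, method = "spearman"), 1)
})

test_that("train_features excludes empty sweeps and tabulates the rest", {
  set.seed(103)
  inp <- gen_correlated_set(0.48)
  rec <- simulate_recording_set(inp, neuron_model(p_spike = 0.3))
  tf <- train_features(rec, tau_w_ms = c(10, 100))
  n_empty <- sum(vapply(rec$sweeps, is_empty_train, TRUE))
  expect_identical(nrow(tf), 55L - n_empty)
  expect_length(attr(tf, "excluded"), n_empty)
  expect_true(all(c("compactness_10", "occupancy_100") %in% names(tf)))
  expect_true(all(tf$firing_rate_hz > 0))
})

test_that("burst probability: trivial and calibrated cases", {
  set.seed(104)
  inp <- gen_correlated_set(0.26)
  # one spike per transmitted pulse -> no bursts
  rec1 <- simulate_recording_set(
    inp, neuron_model(p_spike = 1, latency_ms = 1, jitter_ms = 0,
                      p_burst = 0, refractory_ms = 1e-3))
  expect_equal(p_burst(rec1), 0)
  # every pulse answered by a 2-spike burst -> p(Burst) = 1 (modulo
  # sweep-end clipping, handled by rounding up expectations)
  rec2 <- simulate_recording_set(
    inp, neuron_model(p_spike = 1, latency_ms = 1, jitter_ms = 0,
                      p_burst = 1, burst_geom_p = 1,
                      intra_burst_isi_ms = 1, refractory_ms = 1e-4))
  expect_gt(p_burst(rec2), 0.95)
})

test_that("ISI distribution is a proper 250-bin probability vector", {
  set.seed(105)
  trains <- replicate(20, gen_poisson_train(10), simplify = FALSE)
  d <- isi_distribution(trains)
  expect_length(d$probabilities, 250)
  expect_equal(sum(d$probabilities), 1)
  expect_identical(d$breaks[c(1, 251)], c(0, 50))
  expect_gte(d$overflow_count, 0)
})

test_that("KL burstiness: Gibbs inequality and self-divergence", {
  set.seed(106)
  ref <- replicate(30, gen_poisson_train(10), simplify = FALSE)
  out <- replicate(30, gen_poisson_train(10), simplify = FALSE)
  expect_identical(kl_burstiness(ref, ref), 0)
  expect_gte(kl_burstiness(out, ref), 0)
  # arbitrary distributions: non-negative, zero iff equal
  set.seed(107)
  for (i in 1:20) {
    m <- stats::runif(250); m <- m / sum(m)
    p <- stats::runif(250); p <- p / sum(p)
    expect_gte(kl_divergence(m, p), 0)
  }
  expect_equal(kl_divergence(rep(1 / 250, 250), rep(1 / 250, 250)), 0)
})

test_that("Poisson-like outputs diverge less than bursty outputs", {
  set.seed(108)
  inp <- gen_correlated_set(0.48)
  refs <- unlist(lapply(c(0.26, 0.48, 0.76), function(r) {
    gen_correlated_set(r)$trains
  }), recursive = FALSE)
  rec_gc <- simulate_recording_set(inp, celltype_preset("GC"))
  rec_fs <- simulate_recording_set(inp, celltype_preset("FS"))
  kl_gc <- kl_burstiness(rec_gc$sweeps, refs)
  kl_fs <- kl_burstiness(rec_fs$sweeps, refs)
  expect_gt(kl_fs, kl_gc)
  # a large Poisson set against a Poisson reference sits near zero
  pois_out <- replicate(50, gen_poisson_train(10), simplify = FALSE)
  # "near zero" up to finite-sample histogram noise (250 bins, a few
  # hundred ISIs): well below any bursty preset's divergence
  expect_lt(kl_burstiness(pois_out, refs), 0.5)
  expect_lt(kl_burstiness(pois_out, refs), kl_fs / 2)
})
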