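# Independent oracles used across the suite. These re-derive expected
# values from first principles and deliberately share no code with the
# package implementation paths they check.

# Pointwise evaluation of the SPIKE-dissimilarity profile D(t) straight
# from its definition, one time point at a time.
oracle_spike_d <- function(a_times, b_times, t, duration) {
  s1 <- sort(unique(c(0, a_times, duration)))
  s2 <- sort(unique(c(0, b_times, duration)))
  one <- function(spikes, other, t) {
    t_p <- max(spikes[spikes <= t])
    t_f <- min(spikes[spikes > t])
    x_p <- t - t_p
    x_f <- t_f - t
    x_isi <- t_f - t_p
    d_p <- min(abs(t_p - other))
    d_f <- min(abs(t_f - other))
    c(s = (d_p * x_f + d_f * x_p) / x_isi, isi = x_isi)
  }
  vapply(t, function(tt) {
    u1 <- one(s1, s2, tt)
    u2 <- one(s2, s1, tt)
    (u1["s"] * u2["isi"] + u2["s"] * u1["isi"]) /
      (2 * ((u1["isi"] + u2["isi"]) / 2)^2)
  }, 0)
}

# Dense numerical integration of D(t): subdivide every inter-event
# interval and apply the trapezoid rule to pointwise oracle evaluations.
oracle_spike_similarity <- function(a_times, b_times, duration,
                                    points_per_interval = 64) {
  corners <- sort(unique(c(0, a_times, b_times, duration)))
  total <- 0
  for (k in seq_len(length(corners) - 1L)) {
    lo <- corners[k]; hi <- corners[k + 1L]
    # open-interval grid: avoids the one-sided limits at the corners
    tt <- seq(lo, hi, length.out = points_per_interval + 2L)
    tt <- tt[-c(1L, length(tt))]
    dd <- oracle_spike_d(a_times, b_times, tt, duration)
    h <- tt[2L] - tt[1L]
    # trapezoid over the interior grid plus linear extrapolation to the
    # interval edges (D is linear inside each open interval)
    edge_lo <- dd[1L] - (dd[2L] - dd[1L])
    edge_hi <- dd[length(dd)] + (dd[length(dd)] - dd[length(dd) - 1L])
    vals <- c(edge_lo, dd, edge_hi)
    ww <- c(lo, tt, hi)
    total <- total + sum(diff(ww) * (vals[-1L] + vals[-length(vals)]) / 2)
  }
  1 - total / duration
}

# Brute-force binned similarity metrics written directly from their
# defining sums (no calls into the package or to stats::cor).
oracle_r <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) NaN else num / den
}
oracle_ndp <- function(x, y) {
  den <- sqrt(sum(x^2)) * sqrt(sum(y^2))
  if (den == 0) NaN else sum(x * y) / den
}
oracle_sf <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) NaN else min(nx, ny) / max(nx, ny)
}

# All count vectors of a given length with entries in 0..max_count.
enumerate_count_vectors <- function(n_bins = 4, max_count = 2) {
  as.matrix(expand.grid(rep(list(0:max_count), n_bins)))
}

# Deterministic Poisson-like train for fixtures: fixed times.
fixture_train <- function(times, duration = 2) spike_train(times, duration)
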