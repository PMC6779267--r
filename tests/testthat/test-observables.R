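test_that("static FC reproduces hand-computed correlations", {
  s <- regional_signals(cbind(a = c(0, 1, 2), b = c(0, 2, 1),
                              c = c(0, 1, 2), d = -c(0, 1, 2)), tr = 1)
  fc <- static_fc(s)
  expect_equal(fc$values["a", "b"], 0.5)
  expect_equal(fc$values["a", "c"], 1)
  expect_equal(fc$values["a", "d"], -1)
  expect_equal(fc$values, t(fc$values))
  expect_equal(diag(fc$values), setNames(rep(1, 4), colnames(s$data)))

  s_const <- regional_signals(cbind(c(0, 1, 2), c(1, 1, 1)), tr = 1)
  expect_warning(fc2 <- static_fc(s_const), "constant")
  expect_equal(fc2$values[1, 2], 0)
})

test_that("group FC averages in Fisher-z space", {
  f <- function(r) fc_from_matrix(matrix(c(1, r, r, 1), 2))
  expect_equal(group_average_fc(list(f(0.5), f(0.5)))$values[1, 2], 0.5,
               tolerance = 1e-12)
  expect_equal(group_average_fc(list(f(0.2), f(0.6)))$values[1, 2],
               tanh((atanh(0.2) + atanh(0.6)) / 2), tolerance = 1e-12)
  # idempotence and clipping of |r| = 1
  g <- group_average_fc(list(f(1), f(1)))
  expect_equal(g$values[1, 2], 1, tolerance = 1e-6)
})

test_that("FC similarity correlates strict upper triangles", {
  tri <- function(v) {
    m <- diag(3)
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    fc_from_matrix(m)
  }
  a <- tri(c(0.1, 0.2, 0.3))
  expect_equal(fc_similarity(a, a), 1)
  expect_equal(fc_similarity(a, tri(c(0.3, 0.2, 0.1))), -1)
  expect_equal(fc_similarity(a, tri(-c(0.1, 0.2, 0.3))), -1)
  expect_error(fc_similarity(a, tri(c(0.2, 0.2, 0.2))), "degenerate")
})

test_that("modularity matches the direct double sum", {
  # two disconnected unit-weight dyads
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  expect_equal(fc_modularity(w, c("A", "A", "B", "B")), 0.5)
  # one module telescopes to zero
  expect_equal(fc_modularity(w, rep("A", 4)), 0, tolerance = 1e-15)
  # brute-force oracle on random matrices with random partitions
  for (seed in 1:50) {
    set.seed(seed)
    w <- matrix(runif(100, -0.2, 1), 10)
    w <- (w + t(w)) / 2
    part <- sample(letters[1:3], 10, replace = TRUE)
    expect_equal(fc_modularity(w, part), bf_modularity(w, part),
                 tolerance = 1e-12)
  }
})

test_that("analytic-signal phases track known oscillations", {
  tr <- 0.72
  t <- (0:299) * tr
  s <- regional_signals(cbind(cos(2 * pi * 0.05 * t),
                              cos(2 * pi * 0.05 * t),
                              sin(2 * pi * 0.05 * t)), tr = tr)
  ph <- hilbert_phases(s, trim = 0.1)
  mid <- seq(60, 180)
  # unwrapped phase slope of a cosine equals its angular frequency
  dphi <- diff(ph$phases[mid, 1])
  dphi <- dphi[abs(dphi) < pi]
  expect_lt(abs(median(dphi) / tr - 2 * pi * 0.05), 5e-3)
  # identical signals have zero phase difference everywhere
  expect_equal(max(abs(ph$phases[, 1] - ph$phases[, 2])), 0)
  # sine lags cosine by pi/2
  d13 <- ph$phases[mid, 3] - ph$phases[mid, 1]
  expect_lt(abs(median(d13) + pi / 2), 0.05)
  expect_true(all(ph$phases > -pi & ph$phases <= pi))
})

test_that("instantaneous phase FC is 1 - |sin(dtheta)|", {
  p <- phase_series_from(rbind(c(0, 0, pi / 2, pi / 6)))
  m <- instantaneous_fc(p, 1)
  expect_equal(m[1, 2], 1)          # in phase
  expect_equal(m[1, 3], 0)          # quadrature
  expect_equal(m[1, 4], 0.5)        # sin(pi/6) = 1/2
  expect_equal(diag(m), rep(1, 4))
  expect_true(all(m >= 0 & m <= 1))
  # invariance under a common phase shift
  p2 <- phase_series_from(rbind(c(0, 0, pi / 2, pi / 6) + 0.7))
  expect_equal(instantaneous_fc(p2, 1), m, tolerance = 1e-12)
})

test_that("dFC similarity distribution is exhaustive, seeded, and correct on hand cases", {
  # identical time points: every cosine similarity is 1
  p_same <- phase_series_from(matrix(rep(c(0.3, 1.1, 2.0), each = 4), 4))
  d <- dfc_similarity_distribution(p_same)
  expect_length(d$samples, 4 * 3 / 2)
  expect_true(all(abs(d$samples - 1) < 1e-12))

  # two time points: exactly one sample
  p2 <- phase_series_from(matrix(c(0, 0.5, 1, 0.2, 0.9, 1.7), 2,
                                 byrow = TRUE))
  expect_length(dfc_similarity_distribution(p2)$samples, 1)

  # orthogonal half-vectorized instantaneous FC matrices
  p_orth <- phase_series_from(rbind(c(0, pi / 2, pi),
                                    c(0, pi / 2, pi / 2)))
  # triangles: t1 -> (1-|sin(pi/2)|, 1-|sin(pi)|, 1-|sin(pi/2)|) = (0, 1, 0)
  #            t2 -> (0, 0, 1): orthogonal
  expect_equal(dfc_similarity_distribution(p_orth)$samples, 0,
               tolerance = 1e-12)

  # subsampling is deterministic in the seed and exhaustive under a big cap
  set.seed(42)
  pbig <- phase_series_from(matrix(runif(30 * 4, -pi, pi), 30))
  full <- dfc_similarity_distribution(pbig, max_pairs = 1e6, seed = 1)
  full2 <- dfc_similarity_distribution(pbig, max_pairs = 1e6, seed = 99)
  expect_identical(full$samples, full2$samples)
  sub1 <- dfc_similarity_distribution(pbig, max_pairs = 50, seed = 5)
  sub2 <- dfc_similarity_distribution(pbig, max_pairs = 50, seed = 5)
  expect_identical(sub1$samples, sub2$samples)
  expect_length(sub1$samples, 50)
  nearest <- vapply(sub1$samples,
                    function(x) min(abs(full$samples - x)), numeric(1))
  expect_lt(max(nearest), 1e-12)
})

test_that("KS distance equals the ECDF supremum and the two-sample oracle", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(0, 0), c(1, 1)), 1)
  expect_equal(ks_distance(c(1, 2), c(1, 3)), 0.5)
  for (seed in 1:10) {
    set.seed(seed)
    a <- runif(sample(5:40, 1))
    b <- rbeta(sample(5:40, 1), 2, 1)
    got <- ks_distance(a, b)
    expect_equal(got, bf_ks(a, b), tolerance = 1e-12)
    expect_equal(got, unname(suppressWarnings(
      stats::ks.test(a, b)$statistic)), tolerance = 1e-12)
    expect_equal(got, ks_distance(b, a))
    expect_lte(got, 1)
  }
})

test_that("order parameter matches closed-form phase configurations", {
  p_eq <- phase_series_from(matrix(0.7, 5, 3))
  coh <- order_parameter(p_eq)
  expect_equal(coh$r, rep(1, 5))
  expect_equal(coh$metastability, 0)

  p_bal <- phase_series_from(rbind(c(0, pi / 2, pi, 3 * pi / 2)))
  expect_equal(order_parameter(p_bal)$r, 0, tolerance = 1e-15)

  p_quad <- phase_series_from(rbind(c(0, pi / 2)))
  expect_equal(order_parameter(p_quad)$r, sqrt(2) / 2, tolerance = 1e-15)

  # single oscillator always has r = 1
  p1 <- phase_series_from(matrix(runif(10, -pi, pi), 10, 1))
  expect_equal(order_parameter(p1)$r, rep(1, 10))
})

test_that("intrinsic frequencies come from in-band Welch peaks, median across subjects", {
  tr <- 0.72
  t <- (0:599) * tr
  tone <- function(f, amp = 1) amp * cos(2 * pi * f * t)
  mk <- function(f1) regional_signals(cbind(tone(f1),
                                            tone(0.03, 2) + tone(0.10, 1)),
                                      tr = tr)
  subs <- list(mk(0.04), mk(0.05), mk(0.09))
  om <- estimate_intrinsic_frequencies(subs, band = c(0.02, 0.12))
  bin <- (1 / tr) / 256
  expect_lt(abs(om[[1]] - 2 * pi * 0.05), 2 * pi * bin)  # median peak
  expect_lt(abs(om[[2]] - 2 * pi * 0.03), 2 * pi * bin)  # louder tone wins
  expect_error(estimate_intrinsic_frequencies(subs, band = c(0.5, 0.9)),
               "Nyquist")
})
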