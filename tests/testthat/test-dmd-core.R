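test_that("Hankel embedding lays out shifted copies of the series", {
  expect_equal(build_hankel(c(1, 2, 3, 4), rows = 2, cols = 3),
               matrix(c(1, 2, 2, 3, 3, 4), nrow = 2))
  expect_equal(build_hankel(1:5, rows = 1, cols = 5),
               matrix(1:5, nrow = 1))
  expect_equal(qr(build_hankel(rep(2.5, 10), rows = 4, cols = 7))$rank, 1)
  expect_error(build_hankel(1:3, rows = 2, cols = 3), "too short")
})

test_that("exact DMD recovers the spectrum of a known linear map", {
  # oracle: direct eigendecomposition of the generating matrix
  A <- matrix(c(0.9, 0.2, -0.15, 0.7), 2, 2)
  x <- matrix(0, 2, 12)
  x[, 1] <- c(1, 0.3)
  for (j in 2:12) x[, j] <- A %*% x[, j - 1]
  m <- exact_dmd(snapshot_pair(x), rank_rule = rank_fixed(2))
  expect_equal(sort(Mod(m$eigvals)), sort(Mod(eigen(A)$values)),
               tolerance = 1e-10)
  expect_lt(m$fit_error, 1e-10)

  # scalar geometric decay embedded with two delay rows: one eigenvalue
  s <- 0.9^(0:20)
  D <- build_hankel(s, rows = 2, cols = 20)
  m1 <- exact_dmd(snapshot_pair(D), rank_rule = rank_error(epsilon = 1e-10))
  expect_equal(m1$rank, 1)
  expect_equal(Re(m1$eigvals), 0.9, tolerance = 1e-10)
})

test_that("truncation rules pick the expected ranks and are monotone", {
  p <- three_pair_params()
  s <- damped_sum(p$alpha, p$freq, p$s0)
  D <- build_hankel(s, rows = 40, cols = 61)
  pair <- snapshot_pair(D)
  expect_equal(choose_truncation(pair, rank_error(epsilon = 1e-10)), 6)
  full <- choose_truncation(pair, rank_variance(1.0))
  expect_equal(full, sum(svd(pair$X)$d > 1e-12 * svd(pair$X)$d[1]))
  # rank-2 noiseless data
  D2 <- build_hankel(0.8^(0:30) + 2 * 0.5^(0:30), rows = 5, cols = 27)
  expect_equal(choose_truncation(snapshot_pair(D2),
                                 rank_error(epsilon = 1e-9)), 2)
  # monotonicity: looser tolerance / smaller variance never raises r
  eps_grid <- c(1e-10, 1e-6, 1e-2)
  rs <- vapply(eps_grid, function(e)
    choose_truncation(pair, rank_error(epsilon = e)), integer(1))
  expect_true(all(diff(rs) <= 0))
  q_grid <- c(0.9, 0.99, 0.9999)
  rq <- vapply(q_grid, function(q)
    choose_truncation(pair, rank_variance(q)), integer(1))
  expect_true(all(diff(rq) >= 0))
  # clamping with a warning when the requested rank is unattainable
  expect_warning(choose_truncation(snapshot_pair(D2), rank_fixed(10)),
                 "clamp")
})

test_that("amplitudes are least-squares projections on the modes", {
  d0 <- c(1, 2, 3)
  expect_equal(compute_amplitudes(matrix(d0, ncol = 1), d0),
               as.complex(1))
  modes <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(compute_amplitudes(modes, c(2.5, -1, 0)),
               as.complex(c(2.5, -1)))
  expect_warning(compute_amplitudes(cbind(d0, d0), d0), "degenerate")
})

test_that("Hankel DMD inverts the damped-sinusoid expansion", {
  # single real decaying mode
  s <- exp(-3 * (0:99) * 0.02)
  m <- hankel_dmd(s, rows = 10, rank_rule = rank_fixed(1))
  expect_equal(Re(m$eigvals), exp(-3 * 0.02), tolerance = 1e-9)

  p <- three_pair_params()
  s6 <- damped_sum(p$alpha, p$freq, p$s0)
  m6 <- hankel_dmd(s6, rows = "auto", rank_rule = rank_error())
  expect_equal(m6$rank, 6)
  td <- dplyr::arrange(dplyr::filter(tidy(m6), freq >= 0), freq)
  expect_equal(td$alpha, p$alpha, tolerance = 1e-8)
  expect_equal(td$freq, p$freq, tolerance = 1e-8)
  # embedding invariance: two valid depths agree on (alpha, f)
  m_a <- hankel_dmd(s6, rows = 30, rank_rule = rank_fixed(6))
  m_b <- hankel_dmd(s6, rows = 45, rank_rule = rank_fixed(6))
  f_a <- dplyr::arrange(dplyr::filter(tidy(m_a), freq >= 0), freq)
  f_b <- dplyr::arrange(dplyr::filter(tidy(m_b), freq >= 0), freq)
  expect_equal(f_a$alpha, f_b$alpha, tolerance = 1e-6)
  expect_equal(f_a$freq, f_b$freq, tolerance = 1e-6)
})

test_that("reconstruction satisfies the fit contract", {
  # degenerate single-mode model reproduces a constant
  s_const <- rep(3, 50)
  mc <- hankel_dmd(s_const, rows = 2, rank_rule = rank_fixed(1))
  expect_equal(reconstruct(mc, 10), rep(3, 10), tolerance = 1e-9)

  p <- three_pair_params()
  s6 <- damped_sum(p$alpha, p$freq, p$s0)
  m6 <- hankel_dmd(s6, rows = "auto", rank_rule = rank_error())
  expect_lt(sqrt(sum((reconstruct(m6, 100) - s6)^2) / sum(s6^2)), 1e-8)
})

test_that("real signals give conjugate-closed, non-increasing-error models", {
  set.seed(42)
  for (trial in 1:5) {
    alpha <- sort(stats::runif(3, -7, -2))
    freq <- sort(stats::runif(3, 0.5, 9))
    s0 <- complex(real = stats::rnorm(3), imaginary = stats::rnorm(3))
    s <- damped_sum(alpha, freq, s0) + stats::rnorm(100, 0, 1e-3)
    m <- hankel_dmd(s, rows = 40, rank_rule = rank_fixed(6))
    # conjugate closure of the eigenvalue multiset
    for (mu in m$eigvals) {
      expect_lt(min(Mod(m$eigvals - Conj(mu))), 1e-9)
    }
    # fit error non-increasing in rank
    errs <- vapply(2 * (1:3), function(r)
      hankel_dmd(s, rows = 40, rank_rule = rank_fixed(r))$fit_error,
      numeric(1))
    expect_true(all(diff(errs) <= 1e-12))
  }
})
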