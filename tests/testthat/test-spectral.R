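test_that("eigenvalues follow the quadratic spectrum", {
  expect_equal(drift_eigenvalue(c(0, 1, 5)), c(1, 3, 21))
  expect_true(all(diff(drift_eigenvalue(0:50)) > 0))
})

test_that("spectral coefficients satisfy the closed identities", {
  sc <- spectral_coefficients(0.5, 10)
  expect_equal(sc$b0, 0.5)
  expect_equal(sc$b1, 0.5)
  expect_equal(sc$c[1], 1.5)          # c_0 = 8 w(1/2) * 1.5 / 2
  expect_equal(sc$c[2], 0)            # X_1(1/2) = 0 by parity
  expect_equal(sc$a0, rep(-0.5, 11))
  expect_equal(sc$a1, (-1)^((0:10) + 1) / 2)
  # cross-check against the quadrature norm definition
  for (p in c(0.2, 0.5, 0.73)) {
    scp <- spectral_coefficients(p, 10)
    for (m in 0:10) {
      expect_equal(scp$c[m + 1],
                   p * (1 - p) * gegenbauer_x(m, p) / weighted_norm(m),
                   tolerance = 1e-12)
    }
  }
})

test_that("absorbed starts are degenerate: all series weights vanish", {
  sc0 <- spectral_coefficients(0, 20)
  expect_equal(sc0$c, rep(0, 21))
  expect_equal(sc0$b0, 1)
  expect_equal(sc0$b1, 0)
  d <- suppressWarnings(drift_density(sc0, 0.5, c(0.3, 0.7)))
  expect_equal(d$atom0, 1)
  expect_equal(d$interior, c(0, 0))
})

test_that("density conserves mass and mean and its atoms hit the martingale limits", {
  for (p in c(0.1, 0.4, 0.9)) {
    sc <- spectral_coefficients(p, 100)
    for (t in c(0.05, 0.5, 2)) {
      d <- drift_density(sc, t, xs = numeric(0))
      expect_equal(pair_density(sc, d, function(x) rep(1, length(x)), 0L), 1,
                   tolerance = 1e-8)
      expect_equal(pair_density(sc, d, function(x) x, 1L), p,
                   tolerance = 1e-8)
    }
    dlate <- drift_density(sc, 50, xs = c(0.5))
    expect_equal(dlate$atom0, 1 - p, tolerance = 1e-12)
    expect_equal(dlate$atom1, p, tolerance = 1e-12)
    expect_lt(abs(dlate$interior), 1e-12)
  }
})

test_that("atom masses grow monotonically in time (absorption is irreversible)", {
  sc <- spectral_coefficients(0.35, 100)
  ts <- exp(seq(log(0.05), log(10), length.out = 25))
  atoms <- t(vapply(ts, function(t) {
    d <- drift_density(sc, t, xs = numeric(0))
    c(d$atom0, d$atom1)
  }, numeric(2)))
  expect_true(all(diff(atoms[, 1]) > -1e-12))
  expect_true(all(diff(atoms[, 2]) > -1e-12))
})

test_that("symmetric start gives a symmetric solution", {
  sc <- spectral_coefficients(0.5, 80)
  xs <- seq(0.05, 0.45, by = 0.05)
  d <- drift_density(sc, 1, c(xs, 1 - xs))
  half <- length(xs)
  expect_equal(d$interior[seq_len(half)], d$interior[half + seq_len(half)],
               tolerance = 1e-12)
  expect_equal(d$atom0, d$atom1, tolerance = 1e-12)
})

test_that("the interior series alone is the classical local solution with mass deficit", {
  sc <- spectral_coefficients(0.5, 100)
  xs <- seq(0.02, 0.98, by = 0.02)
  expect_equal(local_density(sc, 1, xs), drift_density(sc, 1, xs)$interior)
  mass <- quad_oracle(function(x) {
    decay <- sc$c * exp(-sc$lambda)
    vals <- rep(0, length(x))
    for (m in 0:sc$M) vals <- vals + decay[m + 1] * gegenbauer_x(m, x)
    vals
  })
  expect_lt(mass, 1)
  expect_equal(mass, coexistence_probability(0.5, 1, 100), tolerance = 1e-8)
  # near t = 0 with many modes the series approximates the initial point mass
  sc_big <- spectral_coefficients(0.5, 300)
  mass0 <- sum(gauss_rule(620)$w * suppressWarnings(
    local_density(sc_big, 0.005, gauss_rule(620)$x)))
  expect_equal(mass0, 1, tolerance = 2e-2)
})

test_that("t = 0 is flagged as the exact point mass at p", {
  sc <- spectral_coefficients(0.4, 50)
  d <- suppressWarnings(drift_density(sc, 0, c(0.4)))
  expect_equal(d$initial_delta_at, 0.4)
  d1 <- drift_density(sc, 1, c(0.4))
  expect_true(is.na(d1$initial_delta_at))
})

test_that("small truncation at small time triggers a warning, not silence", {
  sc <- spectral_coefficients(0.5, 5)
  expect_warning(drift_density(sc, 0.005, c(0.5)), "converges slowly|tail")
  expect_warning(loss_probability(0.5, 0.005, M = 5), "converges slowly|tail")
})

test_that("clamping only affects negative truncation wiggles", {
  sc <- spectral_coefficients(0.2, 12)
  xs <- seq(0.01, 0.99, by = 0.01)
  raw <- suppressWarnings(drift_density(sc, 0.05, xs)$interior)
  cl <- suppressWarnings(drift_density(sc, 0.05, xs, clamp = TRUE)$interior)
  expect_true(any(raw < 0))           # Gibbs artifact present at low M
  expect_true(all(cl >= 0))
  expect_equal(cl[raw >= 0], raw[raw >= 0])
})

test_that("mollified solution equals the interior away from boundaries and bumps carry half mass", {
  sc <- spectral_coefficients(0.4, 80)
  xs <- seq(0.3, 0.7, by = 0.05)
  k <- 80L
  expect_equal(mollified_density(sc, k, 1, xs),
               drift_density(sc, 1, xs)$interior, tolerance = 1e-8)
  # each boundary bump integrates to ~1/2 over [0,1]
  bump_mass <- quad_oracle(function(x) k / sqrt(2 * pi) * exp(-x^2 * k^2 / 2))
  expect_equal(bump_mass, 0.5, tolerance = 1e-6)
  # late time: two bumps weighted by the atom limits 1-p and p
  d <- drift_density(sc, 30, xs = numeric(0))
  near0 <- mollified_density(sc, k, 30, 0)
  expect_equal(near0, d$atom0 * k / sqrt(2 * pi), tolerance = 1e-6)
})

test_that("weak identities hold to truncation accuracy, including at t = 0", {
  sc <- spectral_coefficients(0.3, 100)
  rep_df <- verify_weak_identities(sc, t_grid = c(0.05, 0.5, 1, 5), n_max = 10)
  expect_lt(max(rep_df$residual), 1e-8)
  # spot value against a from-scratch pairing oracle
  lhs <- pairing_oracle(0.3, 0.5, 60, function(x) x * (1 - x))
  expect_equal(lhs, 0.3 * 0.7 * exp(-0.5), tolerance = 1e-9)
  # t = 0: (u(.,0), phi) = phi(p) for the spectral test functions
  d0 <- suppressWarnings(drift_density(sc, 0, xs = numeric(0)))
  for (n in 0:5) {
    phi <- function(x) x * (1 - x) * gegenbauer_x(n, x)
    expect_equal(pair_density(sc, d0, phi, n + 2L), phi(0.3),
                 tolerance = 1e-8)
  }
})

test_that("spectral coefficients survive a JSON round trip", {
  sc <- spectral_coefficients(0.371, 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients_json(sc, path)
  back <- read_coefficients_json(path)
  expect_s3_class(back, "spectral_coefficients")
  expect_equal(back$p, sc$p)
  expect_identical(back$M, sc$M)
  expect_equal(back$c, sc$c)
  expect_equal(back$lambda, sc$lambda)
})
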