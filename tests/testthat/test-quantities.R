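test_that("loss, fixation and coexistence partition the probability", {
  for (p in seq(0.1, 0.9, by = 0.2)) {
    ts <- c(0.05, 0.2, 1, 5, 20)
    s <- loss_probability(p, ts, 100) + fixation_probability(p, ts, 100) +
      coexistence_probability(p, ts, 100)
    expect_equal(s, rep(1, length(ts)), tolerance = 1e-8)
  }
})

test_that("absorption probabilities are monotone with the martingale limits", {
  ts <- exp(seq(log(0.05), log(30), length.out = 30))
  for (p in c(0.3, 0.5, 0.7)) {
    lp <- loss_probability(p, ts, 100)
    fp <- fixation_probability(p, ts, 100)
    cp <- coexistence_probability(p, ts, 100)
    expect_true(all(diff(lp) > -1e-12))
    expect_true(all(diff(fp) > -1e-12))
    expect_true(all(diff(cp) < 1e-12))
    expect_equal(lp[length(ts)], 1 - p, tolerance = 1e-12)
    expect_equal(fp[length(ts)], p, tolerance = 1e-12)
  }
  # symmetric start: loss = fixation at every time
  expect_equal(loss_probability(0.5, ts, 100),
               fixation_probability(0.5, ts, 100), tolerance = 1e-12)
  expect_equal(coexistence_probability(0.5, ts, 100),
               1 - 2 * loss_probability(0.5, ts, 100), tolerance = 1e-10)
  # interior start at early time: essentially nothing absorbed yet
  expect_lt(loss_probability(0.4, 0.01, 400), 1e-3)
  expect_lt(fixation_probability(0.4, 0.01, 400), 1e-3)
})

test_that("late-time coexistence is dominated by the slowest mode", {
  p <- 0.3
  lead <- coexistence_probability(p, 8, 0)    # single term c_0 e^{-t}
  full <- coexistence_probability(p, 8, 100)
  expect_equal(lead, full, tolerance = 1e-8)
  expect_equal(lead, 8 * p * (1 - p) * 1.5 / 2 * exp(-8), tolerance = 1e-14)
})

test_that("mean absorption time: series agrees with the entropy closed form", {
  expect_equal(absorption_mean_closed(0.5), 2 * log(2))
  expect_equal(absorption_mean_closed(0), 0)
  expect_equal(absorption_mean_closed(1), 0)
  expect_equal(absorption_mean_series(0, 200), 0)
  for (p in seq(0.05, 0.95, by = 0.1)) {
    expect_lt(abs(absorption_mean_series(p, 200) - absorption_mean_closed(p)),
              1e-6)
  }
})

test_that("second moment matches the survival-function oracle and variance is positive", {
  # E[T^2] = int_0^infty 2 t P(T > t) dt with P(T > t) the coexistence prob
  for (p in c(0.3, 0.5)) {
    orc <- suppressWarnings(stats::integrate(
      function(t) 2 * t * coexistence_probability(p, t, 200),
      0, 60, rel.tol = 1e-10)$value)
    expect_equal(absorption_second_moment(p, 200), orc, tolerance = 1e-6)
    expect_gt(absorption_variance(p, 200), 0)
  }
  expect_equal(absorption_second_moment(0, 100), 0)
  # term identity: m-th term equals (2 / lambda_{2m}^2) c_{2m}
  p <- 0.3
  sc <- spectral_coefficients(p, 12)
  for (m in 0:5) {
    term <- 64 * p * (1 - p) * (2 * m + 1.5) /
      ((2 * m + 1)^3 * (2 * m + 2)^3) * gegenbauer_x(2 * m, p)
    expect_equal(term, 2 * sc$c[2 * m + 1] / sc$lambda[2 * m + 1]^2,
                 tolerance = 1e-12)
  }
  summ <- absorption_summary(0.5)
  expect_equal(summ$variance, summ$second_moment - summ$mean_series^2)
})

test_that("frequency moments: martingale, initial condition, equilibrium", {
  ts <- c(0, 0.3, 1, 5)
  expect_equal(frequency_moment(1, 0.37, ts), rep(0.37, 4))
  # second moment has the closed form p + (p^2 - p) e^{-t}
  for (p in c(0.25, 0.6)) {
    expect_equal(frequency_moment(2, p, ts, 200),
                 p + (p^2 - p) * exp(-ts), tolerance = 1e-10)
  }
  # t = 0 recovers p^n (slow spectral convergence: many terms, loose tol)
  for (n in 2:5) {
    expect_equal(frequency_moment(n, 0.3, 0, M = 400), 0.3^n, tolerance = 1e-4)
  }
  # t -> infinity: only the atom at 1 contributes x^n
  expect_equal(frequency_moment(4, 0.3, 40), 0.3, tolerance = 1e-12)
})

test_that("series moments equal density-based pairings with atoms", {
  for (n in 2:6) {
    for (t in c(0.1, 1)) {
      orc <- pairing_oracle(0.4, t, 120, function(x) x^n)
      expect_equal(frequency_moment(n, 0.4, t, 120), orc, tolerance = 1e-7)
    }
  }
})

test_that("heterozygosity decays at unit rate and matches the density pairing", {
  expect_equal(heterozygosity(0.5, 0), 0.5)
  expect_equal(heterozygosity(0.5, 1), 0.5 * exp(-1))
  expect_equal(heterozygosity(0.3, 40), 2 * 0.3 * 0.7 * exp(-40))
  for (p in c(0.2, 0.5)) {
    for (t in c(0.1, 1, 3)) {
      orc <- pairing_oracle(p, t, 80, function(x) 2 * x * (1 - x))
      expect_equal(heterozygosity(p, t), orc, tolerance = 1e-8)
    }
  }
})

test_that("absorption-time density is a proper density with the right mean", {
  p <- 0.3
  ts <- seq(0.05, 5, by = 0.05)
  phi <- absorption_time_density(p, ts, 150)
  expect_true(all(phi >= 0))
  # mass below t = 0.01 is vanishingly small for an interior start, and the
  # M = 200 series is fully converged there, so integrate from 0.01
  total <- suppressWarnings(stats::integrate(
    function(t) absorption_time_density(p, t, 200),
    0.01, 80, rel.tol = 1e-9)$value)
  expect_equal(total, 1, tolerance = 1e-6)
  mean_t <- suppressWarnings(stats::integrate(
    function(t) t * absorption_time_density(p, t, 200),
    0.01, 80, rel.tol = 1e-9)$value)
  expect_equal(mean_t, absorption_mean_series(p, 200), tolerance = 1e-6)
  # odd modes contribute nothing: a_{m,0} + a_{m,1} = 0 for odd m
  sc <- spectral_coefficients(p, 11)
  expect_equal(sc$a0[c(2, 4, 6)] + sc$a1[c(2, 4, 6)], rep(0, 3))
})

test_that("quantity series tabulates consistent long-format output", {
  qs <- quantity_series(0.3, M = 100, moments = 2L)
  expect_s3_class(qs, "quantity_series")
  expect_setequal(unique(qs$quantity),
                  c("loss_prob", "fix_prob", "coexist_prob",
                    "heterozygosity", "moment_2"))
  wide <- split(qs$value, qs$quantity)
  expect_equal(wide$loss_prob + wide$fix_prob + wide$coexist_prob,
               rep(1, length(unique(qs$t))), tolerance = 1e-6)
  expect_true(all(diff(wide$heterozygosity) <= 0))
})
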