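test_that("abundance pmf reduces to the geometric at gamma = 1 and
           normalizes", {
  n <- 0:50
  expect_equal(volkov_pmf(n, x = 0.5, gamma = 1), (1 - 0.5) * 0.5^n,
               tolerance = 1e-12)
  expect_equal(volkov_pmf(0:2, 0.5, 1), c(0.5, 0.25, 0.125))
  expect_lt(abs(sum(volkov_pmf(0:3000, x = 0.8, gamma = 2.3)) - 1), 1e-12)
  expect_error(volkov_pmf(1, x = 1.0, gamma = 1), "\\(0, 1\\)")
  expect_error(volkov_pmf(1, x = 0.5, gamma = -1), "gamma")
})

test_that("expected SAD evaluates the printed form with its ratio
           identity and theta-linearity", {
  expect_equal(expected_sad(1, theta = 10, x = 0.5, gamma = 1), 5.0)
  expect_equal(expected_sad(2, theta = 10, x = 0.5, gamma = 1), 2.5)

  th <- 7.3; x <- 0.62; g <- 1.9
  phi <- expected_sad(1:40, th, x, g)
  ratio <- phi[-1] / phi[-40]
  n <- 1:39
  expect_lt(max(abs(ratio - x * (n + g) / (n + 1))), 1e-12)
  expect_equal(expected_sad(1:40, 2 * th, x, g), 2 * phi, tolerance = 1e-12)
  expect_error(expected_sad(0, 1, 0.5, 1), ">= 1")
})

test_that("niche fitting recovers simulated parameters and flags
           degenerate SADs", {
  set.seed(41)
  f <- fit_niche(metaneutral:::rvolkov_zt(200, 0.7, 1.5))
  expect_false(f$flagged)
  expect_lt(abs(f$x - 0.7), 0.1)
  expect_lt(abs(f$gamma - 1.5), 0.6)

  # doubling richness at fixed shape doubles theta
  set.seed(42)
  ab <- metaneutral:::rvolkov_zt(100, 0.6, 1)
  f1 <- fit_niche(ab); f2 <- fit_niche(rep(ab, 2))
  expect_equal(f2$theta / f1$theta, 2, tolerance = 1e-6)
  expect_equal(f1$J, sum(ab))
  expect_equal(f1$S, 100L)

  # all-singleton SAD drives x to the boundary and is flagged
  f3 <- fit_niche(rep(1, 20))
  expect_true(f3$flagged)
  expect_lt(f3$x, 1e-5)

  expect_error(fit_niche(c(0, 2, 3)), ">= 1")
})

test_that("octave binning pools the tail to the expected-count floor", {
  set.seed(1)
  obs <- c(rep(1, 20), rep(2, 8), rep(5, 4), 12, 30)
  ef <- function(n) expected_sad(n, 25, 0.6, 1)
  tf <- function(M) metaneutral:::expected_sad_tail(M, 25, 0.6, 1)
  b <- bin_sad(obs, ef, tf, floor = 1.0)
  expect_true(all(b$E >= 1.0))
  expect_equal(sum(b$O), length(obs))
  # octave structure: first class is [1,1]
  expect_equal(b$lower[1], 1)
  expect_equal(b$upper[1], 1)

  # direct chi-squared arithmetic on two classes
  g <- metaneutral:::sad_gof(data.frame(lower = c(1, 2), upper = c(1, 3),
                                        O = c(8, 12), E = c(10, 10)))
  expect_equal(g$chi2, 0.8)
  expect_equal(g$df, 1L)
  # perfect agreement
  g2 <- metaneutral:::sad_gof(data.frame(lower = 1:2, upper = 1:2,
                                         O = c(5, 5), E = c(5, 5)))
  expect_equal(g2$chi2, 0)
  expect_equal(g2$P, 1)
  expect_equal(g2$R2, 1)
})

test_that("hybrid fit with K = 1 reduces to the single-niche test", {
  m <- gen_hybrid(K = 1, x = 0.7, gamma = 1, S = 60, seed = 8)
  fit <- nnh_fit(m)
  expect_equal(fit$K, 1L)
  if (fit$K_valid == 1L && !is.na(fit$P)) {
    # metacommunity chi2 equals the niche's own local test
    ab <- unclass(m)[unclass(m) > 0]
    f <- fit_niche(ab)
    b <- bin_sad(ab,
                 function(n) expected_sad(n, f$theta, f$x, f$gamma),
                 function(M) metaneutral:::expected_sad_tail(M, f$theta,
                                                             f$x, f$gamma))
    expect_equal(fit$chi2, metaneutral:::sad_gof(b)$chi2, tolerance = 1e-8)
    expect_equal(fit$per_niche$P_local[1], fit$P, tolerance = 1e-8)
  }
})

test_that("local pass counts respect thresholds and the migration
           convention matches the concentration form", {
  m <- gen_hybrid(K = 8, x = 0.7, gamma = 1, S = 40, seed = 9)
  fit <- nnh_fit(m)
  expect_lte(fit$N_pass, fit$K_valid)
  expect_equal(fit$pct_pass, 100 * fit$N_pass / fit$K_valid)

  # raising the threshold can only shrink the passing set
  thresholds <- c(0.05, 0.5, 0.9, 0.95)
  np <- vapply(thresholds, function(t) nnh_local_pass(fit, t)$N_pass, 0)
  expect_true(all(diff(np) <= 0))

  # m = gamma/(gamma + J - 1): J = 164, gamma = 1.236 gives ~0.0075
  expect_equal(1.236 / (1.236 + 164 - 1), 0.00753, tolerance = 1e-3)
  v <- !fit$per_niche$flagged
  expect_equal(fit$per_niche$m[v],
               with(fit$per_niche[v, ], gamma / (gamma + J - 1)))

  # summary row averages equal arithmetic means over valid niches
  expect_equal(fit$row$x, mean(fit$per_niche$x[v]))
  expect_equal(fit$row$J, mean(fit$per_niche$J[v]))
})
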