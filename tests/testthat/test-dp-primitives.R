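test_that("Antoniak pmf matches enumerable cases and normalizes", {
  # N=2: two Chinese-restaurant seatings, s(2,1)=s(2,2)=1
  expect_equal(exp(log_antoniak_pmf(1, theta = 1, N = 2)), 0.5)
  # s(3,3)=1, Gamma(1)/Gamma(4) = 1/6
  expect_equal(exp(log_antoniak_pmf(3, theta = 1, N = 3)), 1 / 6)

  for (theta in c(0.5, 5, 50)) {
    for (N in c(10, 200)) {
      expect_lt(abs(sum(exp(log_antoniak_pmf(1:N, theta, N))) - 1), 1e-10)
    }
  }

  expect_error(log_antoniak_pmf(0, 1, 5), "1 <= S <= N")
  expect_error(log_antoniak_pmf(6, 1, 5), "1 <= S <= N")
  expect_error(log_antoniak_pmf(1, -2, 5), "theta")
})

test_that("CRT sampler matches the exact Stirling pmf", {
  # single customer always opens one table
  expect_true(all(rcrt(50, x = 1, alpha = 7.3) == 1L))

  # exact pmf for x=3, alpha=1 is proportional to s(3,t): (2,3,1)/6
  expect_equal(dcrt(1:3, x = 3, alpha = 1), c(2, 3, 1) / 6)

  set.seed(42)
  for (case in list(c(3, 1), c(6, 0.5))) {
    x <- case[1]; a <- case[2]
    draws <- rcrt(1e5, x, a)
    expected <- dcrt(1:x, x, a)
    obs <- tabulate(draws, x)
    keep <- expected > 1e-9
    gof <- suppressWarnings(
      chisq.test(obs[keep], p = expected[keep] / sum(expected[keep])))
    expect_gt(gof$p.value, 0.01)
  }

  # alpha -> infinity: every customer opens a table
  expect_true(all(rcrt(50, x = 5, alpha = 1e12) == 5L))
  expect_error(rcrt(1, x = 0, alpha = 1), ">= 1")
})

test_that("stick-breaking weights normalize, reproduce, and have the
           Dirichlet-process occupancy expectation", {
  set.seed(7)
  b <- rstick(5, trunc_tol = 1e-10)
  expect_lt(abs(sum(b) - 1), 1e-12)
  expect_true(all(b >= 0))

  set.seed(123); b1 <- rstick(2.5)
  set.seed(123); b2 <- rstick(2.5)
  expect_identical(b1, b2)

  expect_error(rstick(-1), "theta")

  # E[distinct species in N draws] = theta * (digamma(theta+N) - digamma(theta))
  theta <- 5; N <- 100
  target <- dp_expected_richness(theta, N) # ~15.71
  set.seed(99)
  reps <- 2000
  distinct <- replicate(reps, {
    b <- rstick(theta, 1e-10)
    length(unique(sample.int(length(b), N, replace = TRUE, prob = b)))
  })
  se <- sd(distinct) / sqrt(reps)
  expect_lt(abs(mean(distinct) - target), 3 * se)
})

test_that("Dirichlet-multinomial log-likelihood matches closed forms and
           brute-force enumeration", {
  # single category: probability one
  expect_equal(ddirmult(c(2), c(5)), 0)
  # x=(1,1), alpha=(1,1): 2! * G(2)/G(4) = 1/3
  expect_equal(ddirmult(c(1, 1), c(1, 1)), log(1 / 3))

  # brute force over sequential Polya-urn enumeration
  for (case in list(list(x = c(2, 1), a = c(0.5, 1.2)),
                    list(x = c(3, 0, 2), a = c(1, 2, 0.3)),
                    list(x = c(1, 1, 1), a = c(0.7, 0.7, 0.7)))) {
    expect_lt(abs(exp(ddirmult(case$x, case$a)) -
                    dm_pmf_bruteforce(case$x, case$a)), 1e-10)
  }

  # total probability over all outcomes is 1 for N <= 6, S <= 3
  for (N in c(3, 6)) {
    alpha <- c(0.8, 1.5, 2.2)
    xs <- compositions(N, 3L)
    tot <- sum(apply(xs, 1L, function(x) exp(ddirmult(x, alpha))))
    expect_lt(abs(tot - 1), 1e-10)
  }

  # concentration limit: DM -> multinomial as I -> infinity
  beta <- c(0.2, 0.3, 0.5); x <- c(2, 3, 5)
  expect_lt(abs(ddirmult(x, 1e8 * beta) - dmultinom(x, prob = beta, log = TRUE)),
            1e-6)

  expect_error(ddirmult(c(1, 1), c(1, 1), size = 3), "size")
  expect_error(ddirmult(c(1, 1), c(0, 1)), "zero-mass")
})

test_that("immigration rate and migration probability round-trip", {
  I <- c(0.01, 1, 10, 500); N <- c(100, 2000, 50, 5285)
  m <- migration_prob(I, N)
  expect_true(all(m > 0 & m < 1))
  expect_lt(max(abs(immigration_rate(m, N) - I)), 1e-12)
  m2 <- c(1e-4, 0.5, 0.999)
  expect_lt(max(abs(migration_prob(immigration_rate(m2, 300), 300) - m2)),
            1e-12)
})
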