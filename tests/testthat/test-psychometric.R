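test_that("psychometric function hits its analytic anchor points", {
  expect_identical(pf_probability(0, 0.06, 3, lapse = 0.2), 0.5)
  expect_equal(pf_probability(0.06, 0.06, 3, lapse = 0), 0.75)
  # closed form at twice the threshold with unit shape
  expect_equal(pf_probability(0.2, 0.1, 1, lapse = 0), 0.5 + 0.5 * (1 - 2^-2))
  # with a lapse the midpoint sits at 0.75 - lapse/2
  expect_equal(pf_probability(0.1, 0.1, 2, lapse = 0.04), 0.75 - 0.02)
})

test_that("psychometric function is monotone and bounded", {
  set.seed(1)
  for (i in 1:50) {
    th <- runif(1, 0.01, 1)
    beta <- runif(1, 0.3, 8)
    eps <- runif(1, 0, 0.3)
    soa <- sort(runif(20, 0, 2))
    p <- pf_probability(soa, th, beta, eps)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0.5 & p <= 1 - eps))
    # decreasing the threshold can only improve accuracy
    p2 <- pf_probability(soa, th / 2, beta, eps)
    expect_true(all(p2 >= p))
  }
})

test_that("threshold trajectory starts at S, saturates at A, halves on time", {
  S <- log(0.5); A <- log(0.07); R <- 1.4
  expect_equal(threshold_at(1, S, A, R), exp(S))
  expect_equal(threshold_at(5000, S, A, R), exp(A), tolerance = 1e-6)
  expect_equal(threshold_at(17, log(0.2), log(0.2), 2), exp(log(0.2)))
  # half-change identity in log threshold
  expect_equal(log(threshold_at(1 + 10^R, S, A, R)), (S + A) / 2,
               tolerance = 1e-12)
  # monotone decreasing iff S > A; log is affine in the decay kernel
  t <- seq(1, 400, by = 7)
  th <- threshold_at(t, S, A, R)
  expect_true(all(diff(th) < 0))
  q <- 2^(-(t - 1) / 10^R)
  expect_equal(log(th), A + (S - A) * q, tolerance = 1e-14)
  th_up <- threshold_at(t, A, S, R)
  expect_true(all(diff(th_up) > 0))
})

test_that("75% threshold solver matches bisection and round-trips", {
  expect_equal(solve_threshold75(0.1, 3, lapse = 0), 0.1)

  bisect75 <- function(th, beta, eps) {
    f <- function(x) ref_pf(x, th, beta, eps) - 0.75
    lo <- 1e-9; hi <- 100
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  for (case in list(c(0.1, 3, 0.01), c(0.1, 1, 0.24))) {
    x <- solve_threshold75(case[1], case[2], case[3])
    expect_equal(x, bisect75(case[1], case[2], case[3]), tolerance = 1e-7)
    expect_equal(pf_probability(x, case[1], case[2], case[3]), 0.75,
                 tolerance = 1e-9)
  }

  set.seed(2)
  for (i in 1:200) {
    th <- runif(1, 0.005, 2); beta <- runif(1, 0.2, 10)
    eps <- runif(1, 0, 0.24)
    x <- solve_threshold75(th, beta, eps)
    expect_equal(pf_probability(x, th, beta, eps), 0.75, tolerance = 1e-9)
  }
})

test_that("learning magnitude composes the PF with the trajectory", {
  expect_equal(learning_magnitude(log(0.2), log(0.2), 1.5, 3, 0.01,
                                  mean_soa_s = 0.16), 0)
  m <- learning_magnitude(log(0.5), log(0.05), 1.5, 3, 0.01,
                          mean_soa_s = 0.16, t_start = 1, t_end = 200)
  expect_gt(m, 0)
  # equals the direct two-point evaluation composed from the two operations
  th1 <- threshold_at(1, log(0.5), log(0.05), 1.5)
  th2 <- threshold_at(200, log(0.5), log(0.05), 1.5)
  expect_equal(m, pf_probability(0.16, th2, 3, 0.01) -
                 pf_probability(0.16, th1, 3, 0.01))
})

test_that("invalid inputs are rejected", {
  expect_error(pf_probability(-0.1, 0.1, 3), "non-negative")
  expect_error(pf_probability(NA_real_, 0.1, 3), "finite")
  expect_error(pf_probability(0.1, -1, 3), "threshold_s")
  expect_error(pf_probability(0.1, 0.1, 0), "shape")
  expect_error(pf_probability(0.1, 0.1, 3, lapse = 0.6), "lapse")
  expect_error(pf_probability(0.1, 0.1, 3, chance = 0.25), "chance")
  expect_error(threshold_at(0.5, 0, 0, 1), ">= 1")
  expect_error(solve_threshold75(0.1, 3, lapse = 0.3), "unattainable")
  expect_error(learning_magnitude(0, 0, 1, 3, 0.01, mean_soa_s = -1),
               "positive")
  expect_error(learning_magnitude(0, 0, 1, 3, 0.01, mean_soa_s = 0.1,
                                  t_start = 5, t_end = 2), "t_end")
})
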