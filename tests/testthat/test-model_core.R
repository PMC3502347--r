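test_that("expit is the stable inverse logit", {
  expect_equal(expit(0), 0.5)
  expect_equal(expit(-1.896), exp(-1.896) / (1 + exp(-1.896)), tolerance = 1e-12)
  for (eta in c(-700, -30, -1, 0.3, 30, 700)) {
    expect_equal(expit(eta) + expit(-eta), 1, tolerance = 1e-12)
    expect_true(is.finite(expit(eta)))
  }
  # strictly interior wherever doubles can represent it
  for (eta in c(-30, -1, 0.3, 30)) {
    expect_true(expit(eta) > 0 && expit(eta) < 1)
  }
  # no overflow out to |eta| = 700, and the log form keeps resolution there
  expect_identical(expit(c(-745, 745)) >= 0, c(TRUE, TRUE))
  expect_equal(stats::plogis(-700, log.p = TRUE), -700, tolerance = 1e-12)
})

test_that("linear predictor assembles x'xi + z'b and validates inputs", {
  dat <- toyData()
  sp0 <- modelSpec("x", "none", FALSE)
  # intercept-only at zero covariates
  d0 <- longData(data.frame(id = 1, time = 0, x = 0, y = 0))
  expect_equal(
    linearPredictor(d0, sp0, combinedParams(xi = c(-1.3, 5))), -1.3)
  # arithmetic with a random intercept
  sp1 <- modelSpec("x", "intercept", FALSE)
  d1 <- longData(data.frame(id = 1, time = 0, x = 3, y = 0))
  expect_equal(
    linearPredictor(d1, sp1, combinedParams(xi = c(1, 2)), b = matrix(0.5)),
    7.5)
  # random slope multiplies the (centered) time variable
  sp2 <- modelSpec("x", "slope", FALSE, time = "time", time_center = 1)
  eta <- linearPredictor(dat, sp2, combinedParams(xi = c(0, 0)),
                         b = cbind(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(eta, c(1 - 10, 1, 1 + 10, 2 - 20, 2, 3 - 30))
  # a missing covariate is named in the error
  spx <- modelSpec(c("x", "nope"), "none", FALSE)
  expect_error(linearPredictor(dat, spx, combinedParams(xi = rep(0, 3))),
               "nope")
})

test_that("combined conditional log-likelihood matches its closed form", {
  # const = 0 reduces to the Bernoulli log-likelihood
  for (eta in c(-3, -0.5, 0, 1.2, 4)) {
    k <- expit(eta)
    expect_equal(combinedCondLogLik(1, eta, 0), log(k), tolerance = 1e-12)
    expect_equal(combinedCondLogLik(0, eta, 0), log(1 - k), tolerance = 1e-12)
  }
  # hand evaluation: y = 1, eta = 0, const = 1 -> log(0.5/2)
  expect_equal(combinedCondLogLik(1, 0, 1), -2 * log(2), tolerance = 1e-12)
  # general closed form
  for (cst in c(0.1, 0.234, 2)) {
    for (eta in c(-2, 0.7)) {
      k <- expit(eta)
      expect_equal(combinedCondLogLik(1, eta, cst), log(k / (1 + cst)),
                   tolerance = 1e-12)
      expect_equal(combinedCondLogLik(0, eta, cst),
                   log((1 - k + cst) / (1 + cst)), tolerance = 1e-12)
    }
  }
  # stability at extreme linear predictors: finite, no overflow
  expect_true(all(is.finite(combinedCondLogLik(c(1, 0), c(700, -700), 0.5))))
  expect_error(combinedCondLogLik(2, 0, 0.1), "0 or 1")
})

test_that("the two conditional probabilities always sum to one", {
  grid <- expand.grid(eta = seq(-20, 20, length.out = 41),
                      const = c(0, 1e-4, 0.1, 0.234, 1, 10, 1000))
  tot <- exp(combinedCondLogLik(1, grid$eta, 1)) # placeholder shape
  for (i in seq_len(nrow(grid))) {
    s <- exp(combinedCondLogLik(1, grid$eta[i], grid$const[i])) +
      exp(combinedCondLogLik(0, grid$eta[i], grid$const[i]))
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("combined conditional P(y=1) is monotone in eta and const", {
  etas <- seq(-4, 4, by = 0.5)
  p_eta <- exp(combinedCondLogLik(rep(1, length(etas)), etas, 0.3))
  expect_true(all(diff(p_eta) > 0))
  consts <- c(0, 0.05, 0.2, 0.5, 1, 3)
  p_c <- vapply(consts, function(cc) exp(combinedCondLogLik(1, 0.4, cc)),
                numeric(1))
  expect_true(all(diff(p_c) < 0))
})

test_that("beta moments are the textbook mean and variance", {
  expect_equal(unname(betaMoments(1, 1)), c(0.5, 1 / 12), tolerance = 1e-12)
  expect_equal(unname(betaMoments(4, 1.3)["mean"]), 4 / 5.3, tolerance = 1e-10)
  # the ratio link to const
  for (a in c(0.5, 2, 4)) {
    cst <- 0.234
    expect_equal(unname(betaMoments(a, cst * a)["mean"]), 1 / (1 + cst),
                 tolerance = 1e-12)
  }
  # variance via Monte Carlo cross-check
  set.seed(1)
  th <- rbeta(2e5, 2.5, 1.7)
  m <- betaMoments(2.5, 1.7)
  expect_equal(unname(m["mean"]), mean(th), tolerance = 0.005)
  expect_equal(unname(m["variance"]), var(th), tolerance = 0.005)
  expect_error(betaMoments(0, 1), "> 0")
})

test_that("beta-binomial pmf: collapses, oracle sums, and normalization", {
  # uniform-beta, kappa = 1 collapses to the discrete uniform
  for (n in c(1, 3, 10)) {
    expect_equal(dbetabinom(0:n, n, 1, 1, 1), rep(1 / (n + 1), n + 1),
                 tolerance = 1e-12)
  }
  # n = 1 reduces to the combined Bernoulli mean
  expect_equal(dbetabinom(1, 1, 0.7, 3, 2), 0.7 * 3 / 5, tolerance = 1e-12)
  # matches the direct alternating finite sum at small n
  for (n in c(2, 5, 8)) {
    for (kap in c(0.3, 0.9)) {
      for (z in 0:n) {
        expect_equal(dbetabinom(z, n, kap, 2.5, 1.2),
                     altSumBetaBinom(z, n, kap, 2.5, 1.2), tolerance = 1e-10)
      }
    }
  }
  # normalization holds out to n = 50
  for (n in c(7, 25, 50)) {
    for (kap in c(0.2, 0.5, 1)) {
      expect_equal(sum(dbetabinom(0:n, n, kap, 1.8, 0.7)), 1,
                   tolerance = 1e-10)
    }
  }
  expect_error(dbetabinom(5, 3, 0.5, 1, 1), "0 <= z <= n")
})

test_that("beta-binomial pmf equals numeric integration over theta", {
  # brute-force 1-D quadrature of Binomial(z; n, theta*kappa) against the
  # Beta(alpha, beta) density
  oracle <- function(z, n, kap, a, b) {
    stats::integrate(function(th) {
      stats::dbinom(z, n, th * kap) * stats::dbeta(th, a, b)
    }, 0, 1, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }
  expect_equal(dbetabinom(1, 2, 0.5, 2, 2), oracle(1, 2, 0.5, 2, 2),
               tolerance = 1e-9)
  for (n in c(1, 4, 10)) {
    for (kap in c(0.1, 0.5, 0.9)) {
      for (a in c(0.5, 2)) {
        for (b in c(1, 5)) {
          z <- c(0, floor(n / 2), n)
          expect_equal(dbetabinom(z, n, kap, a, b),
                       vapply(z, oracle, numeric(1), n, kap, a, b),
                       tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("dataset-level conditional log-likelihood sums the records", {
  dat <- toyData()
  sp <- modelSpec("x", "intercept", TRUE)
  pr <- combinedParams(xi = c(-0.5, 1), const = 0.3)
  b <- matrix(c(0.2, -0.4, 1), 3, 1)
  eta <- linearPredictor(dat, sp, pr, b)
  expect_equal(conditionalLogLik(dat, sp, pr, b),
               sum(combinedCondLogLik(outcomes(dat), eta, 0.3)),
               tolerance = 1e-12)
  # empty dataset contributes zero
  empty <- dat[0, ]
  attr(empty, "id_col") <- attr(dat, "id_col")
  attr(empty, "time_col") <- attr(dat, "time_col")
  attr(empty, "y_col") <- attr(dat, "y_col")
  class(empty) <- class(dat)
  expect_equal(conditionalLogLik(empty, sp, pr, b), 0)
  # additivity over disjoint subject sets
  d12 <- longData(as.data.frame(dat)[1:5, ], id = "id", time = "time", y = "y")
  d3 <- longData(as.data.frame(dat)[6, , drop = FALSE], id = "id",
                 time = "time", y = "y")
  expect_equal(conditionalLogLik(dat, sp, pr, b),
               conditionalLogLik(d12, sp, pr, b[1:2, , drop = FALSE]) +
                 conditionalLogLik(d3, sp, pr, b[3, , drop = FALSE]),
               tolerance = 1e-12)
  # const is forced off when the spec is not overdispersed
  sp0 <- modelSpec("x", "intercept", FALSE)
  expect_equal(conditionalLogLik(dat, sp0, pr, b),
               sum(combinedCondLogLik(outcomes(dat), eta, 0)),
               tolerance = 1e-12)
})

test_that("reduction ladder: special cases are exact log-likelihood equalities", {
  set.seed(42)
  des <- recoveryDesign(40)
  dat <- simulateDesign(des, seed = 9)
  sp_comb <- recoverySpec()
  sp_ln <- modelSpec(sp_comb$fixed, "intercept", FALSE, time = "time")
  sp_bb <- modelSpec(sp_comb$fixed, "none", TRUE)
  sp_lg <- modelSpec(sp_comb$fixed, "none", FALSE)
  rule <- gaussHermiteRule(12)
  xi <- c(-2, 0.1, 0.4, -0.3)
  # const = 0: combined == logistic-normal
  expect_equal(
    totalLogLik(dat, sp_comb, combinedParams(xi = xi, d0 = 1.5, const = 0), rule),
    totalLogLik(dat, sp_ln, combinedParams(xi = xi, d0 = 1.5), rule),
    tolerance = 1e-12)
  # d = 0: combined == beta-overdispersed logistic
  expect_equal(
    totalLogLik(dat, sp_comb, combinedParams(xi = xi, d0 = 0, const = 0.3), rule),
    totalLogLik(dat, sp_bb, combinedParams(xi = xi, const = 0.3)),
    tolerance = 1e-12)
  # both zero: simple logistic (independent closed form)
  eta <- linearPredictor(dat, sp_lg, combinedParams(xi = xi))
  ll_irls_style <- sum(stats::dbinom(outcomes(dat), 1, expit(eta), log = TRUE))
  expect_equal(
    totalLogLik(dat, sp_comb, combinedParams(xi = xi, d0 = 0, const = 0), rule),
    ll_irls_style, tolerance = 1e-12)
})
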