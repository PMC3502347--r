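test_that("log-posterior blocks match an independent hand summation", {
  dat <- longData(data.frame(id = c(1, 1, 2), time = c(0, 1, 0),
                             x = c(0, 1, 1), y = c(1, 0, 1)))
  sp <- modelSpec("x", "intercept", TRUE)
  pr <- combinedParams(xi = c(0.2, -0.4), alpha = 3.5, beta = 1.2)
  latent <- list(b = matrix(c(0.3, -0.6)), theta = c(0.8, 0.5, 0.9),
                 tau = 2)
  priors <- priorSpec()
  lp <- logPosteriorComponents(dat, sp, pr, latent, priors)
  # hand summation, term by term
  eta <- c(0.2 + 0.3, 0.2 - 0.4 + 0.3, 0.2 - 0.4 - 0.6)
  kap <- 1 / (1 + exp(-eta))
  p <- latent$theta * kap
  h_data <- log(p[1]) + log(1 - p[2]) + log(p[3])
  h_theta <- sum(dbeta(latent$theta, 3.5, 1.2, log = TRUE))
  h_b <- sum(dnorm(c(0.3, -0.6), 0, 1 / sqrt(2), log = TRUE))
  h_tau <- dgamma(2, 0.001, rate = 0.001, log = TRUE)
  h_fix <- sum(dnorm(pr$xi, 0, 1000, log = TRUE)) - log(2) - log(0.4)
  expect_equal(lp$data, h_data, tolerance = 1e-12)
  expect_equal(lp$theta_prior, h_theta, tolerance = 1e-12)
  expect_equal(lp$b_prior, h_b, tolerance = 1e-12)
  expect_equal(lp$tau_prior, h_tau, tolerance = 1e-12)
  expect_equal(lp$fixed_priors, h_fix, tolerance = 1e-12)
  expect_equal(lp$total, h_data + h_theta + h_b + h_tau + h_fix,
               tolerance = 1e-12)
  # theta = 1 reduces the data term to the plain logistic likelihood
  sp0 <- modelSpec("x", "intercept", FALSE)
  lp0 <- logPosteriorComponents(dat, sp0, pr, latent, priors)
  expect_equal(lp0$data, sum(dbinom(outcomes(dat), 1, kap, log = TRUE)),
               tolerance = 1e-12)
  # out-of-range alpha truncates to -Inf, not an error
  pr_out <- combinedParams(xi = c(0.2, -0.4), alpha = 10, beta = 1.2)
  lp_out <- logPosteriorComponents(dat, sp, pr_out, latent, priors)
  expect_identical(lp_out$total, -Inf)
})

test_that("Gelman-Rubin diagnostic behaves across regimes", {
  set.seed(31)
  x <- rnorm(2000)
  # exact copies: no between-chain variance
  expect_equal(gelmanRubin(cbind(x, x)), 1, tolerance = 0.01)
  # two long streams from the same stationary law
  expect_equal(gelmanRubin(cbind(rnorm(5000), rnorm(5000))), 1,
               tolerance = 0.01)
  # disjoint supports blow up
  expect_gt(gelmanRubin(cbind(rnorm(200, 0), rnorm(200, 100))), 10)
  expect_error(gelmanRubin(matrix(rnorm(100), ncol = 1)), "two chains")
})

test_that("posterior summaries: moments, intervals, degenerate draws", {
  set.seed(41)
  d <- cbind(a = rnorm(1e5), b = rnorm(1e5, 2, 0.5))
  s <- posteriorSummary(d)
  expect_equal(s$mean, c(0, 2), tolerance = 0.02)
  expect_equal(s$sd, c(1, 0.5), tolerance = 0.01)
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  expect_identical(s$zero_inside, c(TRUE, FALSE))
  # constant draws collapse
  s0 <- posteriorSummary(matrix(3, 10, 1, dimnames = list(NULL, "c")))
  expect_equal(s0$sd, 0)
  expect_equal(s0$q2.5, s0$q97.5)
  expect_error(posteriorSummary(matrix(numeric(0), 0, 1)), "empty")
})

test_that("DIC from explicit draws matches hand computation exactly", {
  dat <- longData(data.frame(id = c(1, 1, 2), time = c(0, 1, 0),
                             x = c(0, 1, 1), y = c(1, 0, 1)))
  sp <- modelSpec("x", "intercept", TRUE)
  draws <- list(
    xi = rbind(c(0.1, -0.2), c(0.3, 0.1)),
    b = array(c(0.2, -0.1, -0.3, 0.4), dim = c(2, 2, 1)),
    theta = rbind(c(0.9, 0.8, 0.7), c(0.6, 0.95, 0.85)))
  res <- computeDIC(dat, sp, draws)
  # hand computation of the two deviances and the plug-in
  devOf <- function(xi, b, th) {
    eta <- c(xi[1] + b[1], xi[1] + xi[2] + b[1], xi[1] + xi[2] + b[2])
    p <- th / (1 + exp(-eta))
    -2 * (log(p[1]) + log(1 - p[2]) + log(p[3]))
  }
  d1 <- devOf(draws$xi[1, ], draws$b[1, , 1], draws$theta[1, ])
  d2 <- devOf(draws$xi[2, ], draws$b[2, , 1], draws$theta[2, ])
  dbar <- (d1 + d2) / 2
  dhat <- devOf(colMeans(draws$xi), colMeans(draws$b[, , 1]),
                colMeans(draws$theta))
  expect_equal(res$dbar, dbar, tolerance = 1e-12)
  expect_equal(res$dhat, dhat, tolerance = 1e-12)
  expect_equal(res$pd, dbar - dhat, tolerance = 1e-12)
  # identities exact by construction
  expect_identical(res$dic, res$dhat + 2 * res$pd)
  expect_identical(res$dic, res$dbar + res$pd)
  # a point-mass posterior has zero complexity
  pt <- list(xi = rbind(c(0.1, -0.2), c(0.1, -0.2)),
             b = array(0.2, dim = c(2, 2, 1)),
             theta = rbind(c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7)))
  res_pt <- computeDIC(dat, sp, pt)
  expect_equal(res_pt$pd, 0, tolerance = 1e-12)
  expect_equal(res_pt$dic, res_pt$dbar, tolerance = 1e-12)
  expect_error(computeDIC(dat, sp, list(xi = draws$xi)), "draws\\$b")
})

test_that("the sampler is exactly reproducible given a seed", {
  set.seed(57)
  N <- 60
  df <- data.frame(id = 1:N, time = 0, x = rbinom(N, 1, 0.5))
  df$y <- rbinom(N, 1, expit(-0.2 + 0.5 * df$x))
  dat <- longData(df)
  sp <- modelSpec("x", "none", FALSE)
  cfg <- mcmcConfig(n_iter = 400, burn_in = 100, seed = 77)
  f1 <- fitBayes(dat, sp, config = cfg)
  f2 <- fitBayes(dat, sp, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$dic$dic, f2$dic$dic)
  # a different seed moves the draws
  f3 <- fitBayes(dat, sp, config = mcmcConfig(n_iter = 400, burn_in = 100,
                                              seed = 78))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained draws respect the prior truncation and dimensions", {
  set.seed(63)
  des <- toyDesign(40, modelSpec(c("time", "x1"), "intercept", TRUE,
                                 time = "time"),
                   combinedParams(xi = c(-1, 0.1, 0.4), d0 = 1,
                                  alpha = 4, beta = 1.3))
  dat <- simulateDesign(des, seed = 6)
  priors <- priorSpec(alpha_range = c(3, 5), beta_range = c(1.1, 1.5))
  f <- fitBayes(dat, des$spec, priors = priors,
                config = mcmcConfig(n_iter = 600, burn_in = 200, seed = 9))
  pooled <- do.call(rbind, f$draws)
  expect_equal(nrow(pooled), 2 * 400)
  expect_true(all(pooled[, "alpha"] >= 3 & pooled[, "alpha"] <= 5))
  expect_true(all(pooled[, "beta"] >= 1.1 & pooled[, "beta"] <= 1.5))
  expect_true(all(pooled[, "const"] > 0))
  expect_true(all(pooled[, "d0"] > 0))
  th <- f$latent_means$theta
  expect_true(all(th > 0 & th < 1))
  # DIC identities hold on the streaming computation too
  expect_identical(f$dic$dic, f$dic$dhat + 2 * f$dic$pd)
  expect_identical(f$dic$dic, f$dic$dbar + f$dic$pd)
})
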