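# Small simulation designs shared across tests.

# Balanced panel with one between- and one within-type binary covariate.
toyDesign <- function(n_subjects, spec, params, occasions = 0:6) {
  makeDesign("custom", n_subjects = n_subjects, overrides = list(
    occasions = occasions, spec = spec, true_params = params,
    covariates = function(n, occ) {
      J <- length(occ)
      data.frame(id = rep(seq_len(n), each = J),
                 time = rep(occ, n),
                 x1 = rep(stats::rbinom(n, 1L, 0.5), each = J),
                 x2 = rep(stats::rbinom(n, 1L, 0.3), each = J))
    }))
}

# The recovery study conditions: random intercept, strong clustering and
# overdispersion, 7 occasions.
recoverySpec <- function() {
  modelSpec(c("time", "x1", "x2"), "intercept", TRUE, time = "time")
}

recoveryParams <- function() {
  combinedParams(xi = c(`(Intercept)` = -2.5, time = 0.1, x1 = 0.5, x2 = -0.5),
                 d0 = 2, const = 0.25)
}

recoveryDesign <- function(n_subjects = 500) {
  toyDesign(n_subjects, recoverySpec(), recoveryParams())
}

# tiny deterministic dataset for interface tests
toyData <- function() {
  longData(data.frame(
    id = c(1, 1, 1, 2, 2, 3),
    time = c(0, 1, 2, 0, 1, 0),
    x = c(0, 1, 0, 1, 1, 0),
    y = c(0, 1, 0, 1, 0, 1)))
}

# direct alternating-sum evaluation of the beta-binomial pmf (small n only);
# independent of the package's positive-regrouping implementation
altSumBetaBinom <- function(z, n, kappa, alpha, beta) {
  t <- 0:(n - z)
  sum((-1)^t * kappa^(z + t) *
        factorial(n) / (factorial(z) * factorial(t) * factorial(n - z - t)) *
        beta(z + t + alpha, beta) / beta(alpha, beta))
}
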