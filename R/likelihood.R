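#' Inverse-logit link
#'
#' `expit(eta) = exp(eta) / (1 + exp(eta))`, evaluated through
#' [stats::plogis()] so it never overflows for large `|eta|`.
#'
#' @param eta numeric vector of linear-predictor values.
#' @return probabilities in (0, 1).
#' @export
expit <- function(eta) stats::plogis(eta)

#' Linear predictor of the combined model
#'
#' Computes `eta_ij = x_ij' xi + z_ij' b_i` for every record, where `z_ij` is
#' empty, `(1)`, or `(1, t_ij)` according to the random-effects structure and
#' `t_ij` is the (centered) time variable.
#'
#' @param data a [longData] object.
#' @param spec a [modelSpec].
#' @param params a [combinedParams]; only `xi` is used here.
#' @param b per-subject random effects: a matrix with one row per subject and
#'   `nRanef(spec)` columns (a vector is recycled/reshaped), raw scale.
#'   Ignored when `random = "none"`.
#' @return numeric vector of linear predictors, one per record.
#' @export
linearPredictor <- function(data, spec, params, b = NULL) {
  mm <- modelMatrices(data, spec)
  if (length(params$xi) != ncol(mm$X)) {
    stop("length(xi) = ", length(params$xi), " but the fixed-effect design ",
         "has ", ncol(mm$X), " columns (", paste(colnames(mm$X), collapse = ", "), ")")
  }
  eta <- as.vector(mm$X %*% params$xi)
  q <- nRanef(spec)
  if (q > 0L) {
    N <- max(mm$subj)
    if (is.null(b)) b <- matrix(0, N, q)
    b <- matrix(b, ncol = q)
    if (nrow(b) != N) stop("b must have one row per subject (", N, ")")
    eta <- eta + b[mm$subj, 1L]
    if (q == 2L) eta <- eta + b[mm$subj, 2L] * mm$zt
  }
  eta
}

#' Per-observation conditional log-likelihood of the combined model
#'
#' The beta observation effect `theta ~ Beta(alpha, beta)` enters the
#' Bernoulli probability multiplicatively, `P(y = 1 | b, theta) = theta *
#' kappa` with `kappa = expit(eta)`.  Because the Bernoulli likelihood is
#' linear in `theta`, marginalizing it out is closed-form and depends on
#' `(alpha, beta)` only through `const = beta/alpha` (so `E[theta] =
#' 1/(1 + const)`):
#' \deqn{P(y = 1 | b) = \kappa / (1 + const), \quad
#'       P(y = 0 | b) = (1 - \kappa + const) / (1 + const).}
#' Evaluated entirely in log space; `const = 0` recovers the ordinary
#' Bernoulli log-likelihood.
#'
#' @param y 0/1 outcome (vectorized).
#' @param eta linear predictor (vectorized).
#' @param const non-negative overdispersion ratio beta/alpha.
#' @return log-probabilities, same length as `y`/`eta`.
#' @export
combinedCondLogLik <- function(y, eta, const = 0) {
  if (any(!(y %in% c(0, 1)))) stop("y must be 0 or 1")
  if (length(const) != 1L || const < 0) stop("const must be a scalar >= 0")
  n <- max(length(y), length(eta))
  y <- rep_len(y, n)
  eta <- rep_len(eta, n)
  log1c <- log1p(const)
  ll1 <- stats::plogis(eta, log.p = TRUE) - log1c
  l0 <- stats::plogis(-eta, log.p = TRUE)          # log(1 - kappa)
  ll0 <- if (const == 0) l0 else {
    # log(exp(l0) + const) via log-sum-exp
    m <- pmax(l0, log(const))
    m + log(exp(l0 - m) + exp(log(const) - m))
  }
  ll0 <- ll0 - log1c
  ifelse(y == 1, ll1, ll0)
}

#' Moments of the beta observation effect
#'
#' @param alpha,beta positive beta parameters.
#' @return named vector with the mean `alpha/(alpha+beta)` and variance
#'   `alpha*beta/((alpha+beta)^2 (alpha+beta+1))` of `theta ~ Beta(alpha, beta)`.
#' @export
betaMoments <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) stop("alpha and beta must be > 0")
  s <- alpha + beta
  c(mean = alpha / s, variance = alpha * beta / (s^2 * (s + 1)))
}

#' Beta-binomial probability mass with a probability ceiling
#'
#' Probability of `z` successes in `n` conditionally independent Bernoulli
#' trials whose common success probability is `theta * kappa`, with
#' `theta ~ Beta(alpha, beta)` integrated out:
#' \deqn{f(z|n) = \binom{n}{z}\,E[(\theta\kappa)^z (1-\theta\kappa)^{n-z}].}
#' The textbook expansion of this expectation is a finite alternating series
#' in the beta moments, which cancels catastrophically for moderate `n`;
#' writing `1 - kappa*theta = kappa*(1 - theta) + (1 - kappa)` instead gives
#' the identical sum with all terms positive,
#' \deqn{f(z|n) = \sum_{t=0}^{n-z} \frac{n!}{z!\,t!\,(n-z-t)!}
#'   \kappa^{z+t} (1-\kappa)^{n-z-t} \frac{B(z+\alpha,\,t+\beta)}{B(\alpha,\beta)},}
#' accumulated here with log-beta/log-factorial terms.  `kappa = 1` reduces to
#' the standard beta-binomial pmf.
#'
#' @param z,n integer counts, `0 <= z <= n`.
#' @param kappa ceiling probability in (0, 1].
#' @param alpha,beta positive beta parameters.
#' @param log return the log pmf?
#' @return probability (or log-probability); vectorized over `z`.
#' @export
dbetabinom <- function(z, n, kappa, alpha, beta, log = FALSE) {
  stopifnot(length(n) == 1L, length(kappa) == 1L, n >= 0,
            kappa > 0, kappa <= 1, alpha > 0, beta > 0)
  if (any(z < 0 | z > n)) stop("z must satisfy 0 <= z <= n")
  lkap <- base::log(kappa)
  l1mk <- log1p(-kappa)                      # -Inf when kappa == 1
  lbab <- lbeta(alpha, beta)
  out <- vapply(z, function(zi) {
    t <- 0:(n - zi)
    lt <- lgamma(n + 1) - lgamma(zi + 1) - lgamma(t + 1) - lgamma(n - zi - t + 1) +
      (zi + t) * lkap + lbeta(zi + alpha, t + beta) - lbab
    # (1-kappa)^(n-z-t): 0 * log(0) counts as 0 when kappa == 1
    e <- n - zi - t
    lt <- lt + ifelse(e == 0, 0, e * l1mk)
    m <- max(lt)
    if (!is.finite(m)) return(-Inf)
    m + base::log(sum(exp(lt - m)))
  }, numeric(1))
  if (log) out else exp(out)
}

#' Conditional log-likelihood of a dataset given the random effects
#'
#' Sums [combinedCondLogLik()] over all records at each record's linear
#' predictor, with `const` forced to 0 when the spec is not overdispersed.
#' This is the integrand of the subject-level marginal likelihood (the beta
#' effect already marginalized in closed form).
#'
#' @inheritParams linearPredictor
#' @return scalar log-likelihood.
#' @export
conditionalLogLik <- function(data, spec, params, b = NULL) {
  if (nrow(data) == 0L) return(0)
  eta <- linearPredictor(data, spec, params, b)
  cst <- if (spec$overdispersed) params$const else 0
  sum(combinedCondLogLik(outcomes(data), eta, cst))
}
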