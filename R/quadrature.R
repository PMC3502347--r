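#' Gauss-Hermite quadrature rule for normal random effects
#'
#' Probabilists' Gauss-Hermite nodes and weights, scaled so that
#' `sum(w_k * g(n_k))` approximates `E[g(U)]` for `U ~ N(0, 1)` (weights sum
#' to 1).  `dim = 2` returns the tensor-product grid used when both a random
#' intercept and a random slope are present.
#'
#' @param q number of quadrature points per dimension (>= 2).
#' @param dim 1 or 2.
#' @return an object of class `quadratureRule`: a list with `nodes` (a
#'   `q^dim x dim` matrix), `weights`, `log_weights`, `q`, `dim`.
#' @export
gaussHermiteRule <- function(q, dim = 1L) {
  if (q < 2) stop("q must be at least 2")
  stopifnot(dim %in% c(1L, 2L))
  gh <- pracma::gaussHermite(q)          # physicists' rule for exp(-x^2)
  nodes1 <- gh$x * sqrt(2)
  w1 <- gh$w / sqrt(pi)
  if (dim == 1L) {
    nodes <- matrix(nodes1, ncol = 1L)
    w <- w1
  } else {
    g <- expand.grid(k1 = seq_len(q), k2 = seq_len(q))
    nodes <- cbind(nodes1[g$k1], nodes1[g$k2])
    w <- w1[g$k1] * w1[g$k2]
  }
  structure(list(nodes = nodes, weights = w, log_weights = log(w),
                 q = as.integer(q), dim = dim),
            class = "quadratureRule")
}

# log-sum-exp over the rows of matrix M
.rowLogSumExp <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  bad <- !is.finite(m)
  out <- m + log(rowSums(exp(M - m)))
  out[bad] <- -Inf
  out
}

# Matrix-form combined conditional log-likelihood: y a 0/1 vector recycled
# down the columns of the eta matrix.
.cllMatrix <- function(y, ETA, const) {
  log1c <- log1p(const)
  ll1 <- stats::plogis(ETA, log.p = TRUE)
  l0 <- stats::plogis(-ETA, log.p = TRUE)
  ll0 <- if (const == 0) l0 else {
    m <- pmax(l0, log(const))
    m + log(exp(l0 - m) + const * exp(-m))
  }
  ll0 + y * (ll1 - ll0) - log1c
}

# Precomputed pieces of the marginal likelihood for one (data, spec) pair.
.llEngine <- function(data, spec) {
  mm <- modelMatrices(data, spec)
  list(y = outcomes(data), X = mm$X, zt = mm$zt, subj = mm$subj,
       N = max(mm$subj), nre = nRanef(spec), overdispersed = spec$overdispersed,
       ids = unique(subjectIds(data)))
}

# Per-subject marginal log-likelihood given an engine and raw parameters.
.subjectMarginals <- function(eng, xi, d0, d1, const, rule, adaptive = FALSE) {
  cst <- if (eng$overdispersed) const else 0
  xb <- drop(eng$X %*% xi)
  if (eng$nre == 0L) {
    ll <- combinedCondLogLik(eng$y, xb, cst)
    return(drop(rowsum(ll, eng$subj)))
  }
  if (adaptive) {
    return(.subjectMarginalsAdaptive(eng, xb, d0, d1, cst, rule))
  }
  U <- rule$nodes
  K <- nrow(U)
  n <- length(xb)
  OFF <- tcrossprod(rep(1, n), d0 * U[, 1L])
  if (eng$nre == 2L) OFF <- OFF + tcrossprod(eng$zt, d1 * U[, 2L])
  LL <- .cllMatrix(eng$y, xb + OFF, cst)
  S <- rowsum(LL, eng$subj)                                 # N x K
  .rowLogSumExp(S + rep(rule$log_weights, each = eng$N))
}

# Adaptive (mode/curvature-recentered) Gauss-Hermite: per-subject Newton on
# the standardized-effect posterior, then the recentered rule.
.subjectMarginalsAdaptive <- function(eng, xb, d0, d1, cst, rule) {
  q <- eng$nre
  N <- eng$N
  scale <- c(d0, d1)[seq_len(q)]
  # g_i(U): per-subject conditional loglik + standard-normal log prior
  gfun <- function(U) {                                     # U is N x q
    eta <- xb + scale[1L] * U[eng$subj, 1L]
    if (q == 2L) eta <- eta + scale[2L] * U[eng$subj, 2L] * eng$zt
    drop(rowsum(combinedCondLogLik(eng$y, eta, cst), eng$subj)) -
      0.5 * rowSums(U^2) - 0.5 * q * log(2 * pi)
  }
  M <- matrix(0, N, q)
  h <- 1e-3
  for (iter in 1:25) {
    step_total <- 0
    for (d in seq_len(q)) {
      Up <- M; Up[, d] <- M[, d] + h
      Um <- M; Um[, d] <- M[, d] - h
      f0 <- gfun(M); fp <- gfun(Up); fm <- gfun(Um)
      g1 <- (fp - fm) / (2 * h)
      g2 <- (fp - 2 * f0 + fm) / h^2
      g2 <- pmin(g2, -1e-4)                                 # keep concave
      step <- pmax(pmin(-g1 / g2, 1), -1)                   # damped Newton
      M[, d] <- M[, d] + step
      step_total <- step_total + max(abs(step))
    }
    if (step_total < 1e-8) break
  }
  # curvature-based scales per dimension
  S2 <- matrix(1, N, q)
  for (d in seq_len(q)) {
    Up <- M; Up[, d] <- M[, d] + h
    Um <- M; Um[, d] <- M[, d] - h
    g2 <- (gfun(Up) - 2 * gfun(M) + gfun(Um)) / h^2
    S2[, d] <- 1 / sqrt(pmax(-g2, 1e-4))
  }
  X <- rule$nodes
  K <- nrow(X)
  A <- matrix(-Inf, N, K)
  lphi <- rowSums(matrix(stats::dnorm(X, log = TRUE), K, q))
  for (k in seq_len(K)) {
    Uk <- M + S2 * rep(X[k, ], each = N)
    A[, k] <- rule$log_weights[k] - lphi[k] + gfun(Uk)
  }
  .rowLogSumExp(A) + rowSums(log(S2))
}

#' Subject-level marginal log-likelihood
#'
#' For each subject, integrates the conditional likelihood (beta effect
#' already marginalized in closed form) over the normal random effects with a
#' Gauss-Hermite rule; with no random effects this is the conditional
#' log-likelihood at `b = 0`.  The integral is accumulated by log-sum-exp
#' over the nodes.
#'
#' @inheritParams linearPredictor
#' @param rule a [gaussHermiteRule()] whose dimension matches the
#'   random-effects structure (ignored when `random = "none"`).
#' @param adaptive recenter and rescale the rule at each subject's
#'   conditional mode (helps when the random-effect SD is large)?
#' @return named numeric vector, one log-likelihood per subject.
#' @export
subjectLogLik <- function(data, spec, params, rule = NULL, adaptive = FALSE) {
  eng <- .llEngine(data, spec)
  if (eng$nre > 0L) {
    if (is.null(rule)) rule <- gaussHermiteRule(10L, eng$nre)
    if (rule$dim != eng$nre) {
      stop("quadrature rule dimension (", rule$dim,
           ") does not match the random-effects structure (", eng$nre, ")")
    }
  }
  out <- .subjectMarginals(eng, params$xi, params$d0, params$d1,
                           params$const, rule, adaptive)
  if (any(!is.finite(out))) {
    stop("non-finite marginal log-likelihood for subject(s): ",
         paste(utils::head(eng$ids[!is.finite(out)], 5L), collapse = ", "))
  }
  stats::setNames(out, eng$ids)
}

#' Total marginal log-likelihood
#'
#' Sum of [subjectLogLik()] over subjects (subjects are independent).
#'
#' @inheritParams subjectLogLik
#' @return scalar log-likelihood.
#' @export
totalLogLik <- function(data, spec, params, rule = NULL, adaptive = FALSE) {
  sum(subjectLogLik(data, spec, params, rule, adaptive))
}
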