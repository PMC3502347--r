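# Conditional data log-likelihood given (eta, theta): P(y=1) = theta * kappa.
# 1 - theta*kappa is computed as (1-kappa) + (1-theta)*kappa, which stays
# accurate when kappa is near 1.
.dataLL <- function(y, eta, theta) {
  lkap <- stats::plogis(eta, log.p = TRUE)
  k1m <- stats::plogis(-eta)
  ll0 <- log(k1m + (1 - theta) * (1 - k1m))
  y * (log(theta) + lkap) + (1 - y) * ll0
}

#' Unnormalized log-posterior, by block
#'
#' Evaluates the five building blocks of the posterior at an explicit state:
#' the conditional Bernoulli data log-likelihood given `(b, theta)` (success
#' probability `theta * kappa`), the beta log-prior of `theta`, the normal
#' log-prior of `b` given the precisions `tau`, the Gamma log-prior of `tau`,
#' and the (diffuse normal / box-uniform) log-priors of `xi` and
#' `(alpha, beta)`.  States outside the prior support (a `theta` outside
#' (0,1), `alpha` or `beta` outside its uniform range) give `-Inf` blocks,
#' not an error.
#'
#' @inheritParams linearPredictor
#' @param latent list with `b` (N x q matrix, or NULL), `theta` (per-record
#'   vector in (0,1), or NULL for the non-overdispersed variants), `tau`
#'   (per-random-effect precisions).
#' @param priors a [priorSpec].
#' @return named list `data`, `theta_prior`, `b_prior`, `tau_prior`,
#'   `fixed_priors`, and their `total`.
#' @export
logPosteriorComponents <- function(data, spec, params, latent, priors) {
  eng <- .llEngine(data, spec)
  eta <- linearPredictor(data, spec, params, latent$b)
  theta <- if (spec$overdispersed) latent$theta else rep(1, nrow(data))
  alpha <- params$alpha
  beta <- params$beta
  lp_theta <- 0
  if (spec$overdispersed) {
    if (any(theta <= 0) || any(theta >= 1)) {
      lp_theta <- -Inf
    } else {
      lp_theta <- sum(stats::dbeta(theta, alpha, beta, log = TRUE))
    }
  }
  lp_fix <- sum(stats::dnorm(params$xi, 0, 1 / sqrt(priors$xi_prec), log = TRUE))
  if (spec$overdispersed) {
    inbox <- alpha >= priors$alpha_range[1] && alpha <= priors$alpha_range[2] &&
      beta >= priors$beta_range[1] && beta <= priors$beta_range[2]
    lp_fix <- lp_fix + if (inbox) {
      -log(diff(priors$alpha_range)) - log(diff(priors$beta_range))
    } else -Inf
  }
  lp_b <- lp_tau <- 0
  if (eng$nre > 0L) {
    tau <- latent$tau
    for (d in seq_len(eng$nre)) {
      lp_b <- lp_b + sum(stats::dnorm(latent$b[, d], 0, 1 / sqrt(tau[d]),
                                      log = TRUE))
    }
    lp_tau <- sum(stats::dgamma(tau, priors$tau_shape, rate = priors$tau_rate,
                                log = TRUE))
  }
  ldata <- if (is.finite(lp_theta)) sum(.dataLL(eng$y, eta, theta)) else -Inf
  out <- list(data = ldata, theta_prior = lp_theta, b_prior = lp_b,
              tau_prior = lp_tau, fixed_priors = lp_fix)
  out$total <- Reduce(`+`, out[1:5])
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio: with `m` chains of length
#' `n`, `R-hat = sqrt(((n-1)/n * W + B/n) / W)`.  Values near 1 indicate the
#' chains have mixed.
#'
#' @param draws a matrix with one column per chain (equal lengths), or a list
#'   of equal-length numeric vectors.
#' @return scalar R-hat.
#' @export
gelmanRubin <- function(draws) {
  if (is.list(draws) && !is.matrix(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  m <- ncol(draws)
  n <- nrow(draws)
  if (m < 2L) stop("at least two chains are required")
  if (n < 10L) stop("chains must have length >= 10")
  means <- colMeans(draws)
  W <- mean(apply(draws, 2, stats::var))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary table
#'
#' Mean, SD, and equal-tail 95% credible interval per parameter, plus a flag
#' for whether 0 lies inside the interval (the usual credible-interval
#' significance device).
#'
#' @param draws a matrix of draws (rows = iterations, columns = parameters)
#'   or a list of per-chain matrices, pooled after burn-in.
#' @return data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `zero_inside`.
#' @export
posteriorSummary <- function(draws) {
  if (is.list(draws) && !is.matrix(draws)) draws <- do.call(rbind, draws)
  draws <- as.matrix(draws)
  if (nrow(draws) == 0L) stop("empty draws")
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             q2.5 = qs[1, ], q97.5 = qs[2, ],
             zero_inside = qs[1, ] <= 0 & qs[2, ] >= 0,
             row.names = NULL)
}

#' Deviance information criterion from explicit draws
#'
#' Deviance is focused conditionally on the latent states:
#' `D = -2 * sum log P(y_ij | xi, b_i, theta_ij)` with success probability
#' `theta * kappa`.  `dbar` averages the deviance over draws, `dhat` plugs in
#' the posterior means of `xi`, `b` and `theta`, `pd = dbar - dhat`, and
#' `dic = dhat + 2 pd = dbar + pd` (identities exact by construction).
#' [fitBayes()] computes the same quantities in a streaming fashion; this
#' function serves explicit (small) draw sets.
#'
#' @inheritParams linearPredictor
#' @param draws list with `xi` (R x p matrix), and as required by the spec
#'   `b` (R x N x q array) and `theta` (R x n_obs matrix).
#' @return an object of class `dicResult`: list `dbar`, `dhat`, `pd`, `dic`.
#' @export
computeDIC <- function(data, spec, draws) {
  eng <- .llEngine(data, spec)
  R <- nrow(draws$xi)
  nre <- eng$nre
  if (nre > 0L && is.null(draws$b)) stop("draws$b required for this spec")
  if (spec$overdispersed && is.null(draws$theta)) {
    stop("draws$theta required for an overdispersed spec")
  }
  dev1 <- function(xi, b, theta) {
    pr <- combinedParams(xi = xi)
    eta <- linearPredictor(data, spec, pr, b)
    -2 * sum(.dataLL(eng$y, eta, theta))
  }
  devs <- vapply(seq_len(R), function(r) {
    b <- if (nre > 0L) matrix(draws$b[r, , ], ncol = nre) else NULL
    th <- if (spec$overdispersed) draws$theta[r, ] else rep(1, nrow(data))
    dev1(draws$xi[r, ], b, th)
  }, numeric(1))
  dbar <- mean(devs)
  bbar <- if (nre > 0L) matrix(apply(draws$b, c(2, 3), mean), ncol = nre) else NULL
  thbar <- if (spec$overdispersed) colMeans(draws$theta) else rep(1, nrow(data))
  dhat <- dev1(colMeans(draws$xi), bbar, thbar)
  .dicResult(dbar, dhat)
}

.dicResult <- function(dbar, dhat) {
  pd <- dbar - dhat
  structure(list(dbar = dbar, dhat = dhat, pd = pd, dic = dhat + 2 * pd),
            class = "dicResult")
}

#' @export
print.dicResult <- function(x, ...) {
  cat("DIC = ", format(x$dic, nsmall = 1), "  (pD = ", format(x$pd, nsmall = 1),
      ", mean deviance = ", format(x$dbar, nsmall = 1), ")\n", sep = "")
  invisible(x)
}

#' Bayesian fit by Metropolis-within-Gibbs MCMC
#'
#' Samples the posterior of any of the four model variants with the study
#' priors: diffuse normals on the fixed effects, Gamma(0.001, 0.001) on each
#' random-effect precision, and box-uniform priors (lower bounds > 1) on the
#' beta parameters.  Updates per sweep: random-walk Metropolis on each fixed
#' effect, vectorized per-subject random-walk Metropolis on each random-effect
#' column, a Gibbs draw of the precisions, an exact conjugate Gibbs draw of
#' every beta observation effect (`y = 1` gives Beta(alpha+1, beta); `y = 0` a
#' two-component Beta(alpha, beta) / Beta(alpha, beta+1) mixture), and a joint
#' random-walk on `(alpha, beta)` inside the prior box.  Proposal scales adapt
#' toward ~44% acceptance during burn-in and are frozen afterwards.  Chains
#' start from overdispersed points; runs are exactly reproducible given the
#' config seed.
#'
#' @param data a [longData].
#' @param spec a [modelSpec].
#' @param priors a [priorSpec].
#' @param config an [mcmcConfig]; `n_iter = NULL` picks the variant default
#'   (70,000 combined, 50,000 otherwise, 10,000 burn-in).
#' @param verbose print progress?
#' @return an object of class `combFitBayes`: per-chain retained `draws`
#'   (matrices, one column per reported parameter), `summaries` (posterior
#'   mean/SD/95% interval/R-hat), `dic` (a `dicResult`), posterior means of
#'   the latent states, acceptance rates and the config.
#' @export
fitBayes <- function(data, spec, priors = priorSpec(), config = mcmcConfig(),
                     verbose = FALSE) {
  eng <- .llEngine(data, spec)
  y <- eng$y
  X <- eng$X
  n <- length(y)
  p <- ncol(X)
  nre <- eng$nre
  over <- spec$overdispersed
  n_iter <- config$n_iter
  if (is.null(n_iter)) n_iter <- if (variantName(spec) == "combined") 70000L else 50000L
  burn <- config$burn_in
  stopifnot(n_iter > burn)
  thin <- config$thin
  keep_idx <- seq.int(burn + 1L, n_iter, by = thin)
  R <- length(keep_idx)

  g0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  xi_start <- g0$coefficients
  if (any(!is.finite(xi_start))) stop("non-finite initial state from logistic fit")
  # rough per-coefficient scales from the IRLS weights
  W <- g0$weights
  xtx <- crossprod(X * sqrt(W))
  xi_se <- sqrt(diag(tryCatch(solve(xtx), error = function(e) diag(1, p))))

  par_names <- c(colnames(X),
                 if (nre >= 1L) "d0", if (nre == 2L) "d1",
                 if (over) c("alpha", "beta", "const"))
  chains <- vector("list", config$n_chains)
  dev_draws <- vector("list", config$n_chains)
  acc_rates <- vector("list", config$n_chains)
  sum_b <- if (nre > 0L) matrix(0, eng$N, nre) else NULL
  sum_theta <- if (over) numeric(n) else NULL
  sum_xi <- numeric(p)
  dev_sum <- 0

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * ch)
    disp <- if (ch == 1L) 0 else 1   # overdispersed start for later chains
    xi <- xi_start + disp * stats::rnorm(p, 0, 2 * xi_se)
    b <- if (nre > 0L) matrix(disp * stats::rnorm(eng$N * nre), eng$N, nre) else NULL
    tau <- rep(if (ch == 1L) 1 else 0.2, max(nre, 1L))
    alpha <- beta <- NA_real_
    theta <- NULL
    if (over) {
      alpha <- if (ch == 1L) mean(priors$alpha_range) else
        priors$alpha_range[1] + 0.9 * diff(priors$alpha_range)
      beta <- if (ch == 1L) mean(priors$beta_range) else
        priors$beta_range[1] + 0.9 * diff(priors$beta_range)
      theta <- stats::rbeta(n, alpha, beta)
      theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
    }
    eta <- drop(X %*% xi)
    if (nre >= 1L) eta <- eta + b[eng$subj, 1L]
    if (nre == 2L) eta <- eta + b[eng$subj, 2L] * eng$zt
    th1 <- if (over) theta else rep(1, n)
    ll_obs <- .dataLL(y, eta, th1)
    if (any(!is.finite(ll_obs))) stop("non-finite initial state")

    s_xi <- 2.4 * xi_se
    s_b <- rep(1, max(nre, 1L))
    s_ab <- c(diff(priors$alpha_range), diff(priors$beta_range)) / 10
    acc_xi <- rej_xi <- numeric(p)
    acc_b <- rej_b <- numeric(max(nre, 1L))
    acc_ab <- rej_ab <- 0
    consec_rej <- stats::setNames(numeric(p + nre + over),
                                  c(paste0("xi", seq_len(p)),
                                    if (nre > 0L) paste0("b", seq_len(nre)),
                                    if (over) "ab"))
    warned_stuck <- FALSE
    draws <- matrix(NA_real_, R, length(par_names),
                    dimnames = list(NULL, par_names))
    devs <- numeric(R)
    r <- 0L

    for (it in seq_len(n_iter)) {
      ## fixed effects, componentwise RW
      for (k in seq_len(p)) {
        dlt <- stats::rnorm(1, 0, s_xi[k])
        eta_new <- eta + dlt * X[, k]
        ll_new <- .dataLL(y, eta_new, th1)
        lr <- sum(ll_new) - sum(ll_obs) -
          0.5 * priors$xi_prec * ((xi[k] + dlt)^2 - xi[k]^2)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          xi[k] <- xi[k] + dlt; eta <- eta_new; ll_obs <- ll_new
          acc_xi[k] <- acc_xi[k] + 1; consec_rej[k] <- 0
        } else {
          rej_xi[k] <- rej_xi[k] + 1
          consec_rej[k] <- consec_rej[k] + 1
        }
      }
      ## random effects, vectorized per-subject RW per column
      if (nre > 0L) {
        for (d in seq_len(nre)) {
          step <- stats::rnorm(eng$N, 0, s_b[d])
          dEta <- step[eng$subj]
          if (d == 2L) dEta <- dEta * eng$zt
          ll_new <- .dataLL(y, eta + dEta, th1)
          dsubj <- drop(rowsum(ll_new - ll_obs, eng$subj))
          lpr <- -0.5 * tau[d] * ((b[, d] + step)^2 - b[, d]^2)
          acc <- log(stats::runif(eng$N)) < dsubj + lpr
          if (any(acc)) {
            b[acc, d] <- b[acc, d] + step[acc]
            upd <- acc[eng$subj]
            eta[upd] <- eta[upd] + dEta[upd]
            ll_obs[upd] <- ll_new[upd]
          }
          acc_b[d] <- acc_b[d] + mean(acc)
          rej_b[d] <- rej_b[d] + 1 - mean(acc)
          consec_rej[p + d] <- if (any(acc)) 0 else consec_rej[p + d] + 1
        }
        ## precisions, Gibbs
        for (d in seq_len(nre)) {
          tau[d] <- stats::rgamma(1, priors$tau_shape + eng$N / 2,
                                  rate = priors$tau_rate + sum(b[, d]^2) / 2)
        }
      }
      ## beta observation effects, exact conjugate Gibbs
      if (over) {
        kap <- stats::plogis(eta)
        i1 <- y == 1L
        theta[i1] <- stats::rbeta(sum(i1), alpha + 1, beta)
        if (any(!i1)) {
          k0 <- kap[!i1]
          # mixture: (1-kappa) B(a,b) * Beta(a,b)  +  kappa B(a,b+1) * Beta(a,b+1)
          l1 <- log1p(-k0) + lbeta(alpha, beta)
          l2 <- log(k0) + lbeta(alpha, beta + 1)
          p2 <- 1 / (1 + exp(l1 - l2))
          pick2 <- stats::runif(sum(!i1)) < p2
          bb <- ifelse(pick2, beta + 1, beta)
          theta[!i1] <- stats::rbeta(sum(!i1), alpha, bb)
        }
        theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
        th1 <- theta
        ll_obs <- .dataLL(y, eta, th1)
        ## (alpha, beta), joint RW inside the prior box
        an <- alpha + stats::rnorm(1, 0, s_ab[1])
        bn <- beta + stats::rnorm(1, 0, s_ab[2])
        if (an >= priors$alpha_range[1] && an <= priors$alpha_range[2] &&
            bn >= priors$beta_range[1] && bn <= priors$beta_range[2]) {
          lr <- sum(stats::dbeta(theta, an, bn, log = TRUE)) -
            sum(stats::dbeta(theta, alpha, beta, log = TRUE))
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            alpha <- an; beta <- bn
            acc_ab <- acc_ab + 1; consec_rej[p + nre + 1L] <- 0
          } else {
            rej_ab <- rej_ab + 1
            consec_rej[p + nre + 1L] <- consec_rej[p + nre + 1L] + 1
          }
        } else {
          rej_ab <- rej_ab + 1
          consec_rej[p + nre + 1L] <- consec_rej[p + nre + 1L] + 1
        }
      }
      if (!warned_stuck && any(consec_rej >= 1000)) {
        warning("a Metropolis block rejected 1000 consecutive proposals ",
                "(block ", names(consec_rej)[which.max(consec_rej)], ")")
        warned_stuck <- TRUE
      }
      ## proposal adaptation during burn-in only
      if (it <= burn && it %% 50L == 0L) {
        rate_xi <- acc_xi / pmax(acc_xi + rej_xi, 1)
        s_xi <- s_xi * exp(0.3 * (rate_xi - 0.44))
        if (nre > 0L) {
          rate_b <- acc_b / pmax(acc_b + rej_b, 1)
          s_b <- s_b * exp(0.3 * (rate_b - 0.44))
        }
        if (over) {
          rate_ab <- acc_ab / max(acc_ab + rej_ab, 1)
          s_ab <- s_ab * exp(0.3 * (rate_ab - 0.3))
        }
        acc_xi[] <- rej_xi[] <- 0
        acc_b[] <- rej_b[] <- 0
        acc_ab <- rej_ab <- 0
      }
      ## retain
      if (it > burn && (it - burn - 1L) %% thin == 0L) {
        r <- r + 1L
        row <- c(xi,
                 if (nre >= 1L) 1 / sqrt(tau[1L]),
                 if (nre == 2L) 1 / sqrt(tau[2L]),
                 if (over) c(alpha, beta, beta / alpha))
        draws[r, ] <- row
        devs[r] <- -2 * sum(ll_obs)
        sum_xi <- sum_xi + xi
        if (nre > 0L) sum_b <- sum_b + b
        if (over) sum_theta <- sum_theta + theta
        dev_sum <- dev_sum + devs[r]
      }
      if (verbose && it %% 5000L == 0L) {
        message("chain ", ch, ": iteration ", it, "/", n_iter)
      }
    }
    chains[[ch]] <- draws
    dev_draws[[ch]] <- devs
    acc_rates[[ch]] <- list(
      xi = acc_xi / pmax(acc_xi + rej_xi, 1),
      b = if (nre > 0L) acc_b / pmax(acc_b + rej_b, 1),
      alpha_beta = if (over) acc_ab / max(acc_ab + rej_ab, 1))
  }

  Rtot <- R * config$n_chains
  xi_bar <- sum_xi / Rtot
  b_bar <- if (nre > 0L) sum_b / Rtot else NULL
  theta_bar <- if (over) sum_theta / Rtot else rep(1, n)
  eta_bar <- drop(X %*% xi_bar)
  if (nre >= 1L) eta_bar <- eta_bar + b_bar[eng$subj, 1L]
  if (nre == 2L) eta_bar <- eta_bar + b_bar[eng$subj, 2L] * eng$zt
  dhat <- -2 * sum(.dataLL(y, eta_bar, theta_bar))
  dic <- .dicResult(dev_sum / Rtot, dhat)

  summ <- posteriorSummary(chains)
  summ$rhat <- if (config$n_chains >= 2L) {
    vapply(seq_along(par_names), function(j) {
      gelmanRubin(lapply(chains, function(m) m[, j]))
    }, numeric(1))
  } else NA_real_

  structure(list(
    spec = spec, priors = priors,
    config = list(n_iter = n_iter, burn_in = burn, n_chains = config$n_chains,
                  seed = config$seed, thin = thin, retained = R),
    draws = chains, deviance_draws = dev_draws,
    summaries = summ, dic = dic,
    latent_means = list(b = b_bar, theta = if (over) theta_bar else NULL,
                        xi = xi_bar),
    acceptance = acc_rates,
    n_subjects = eng$N, n_obs = n,
    data_fingerprint = .dataFingerprint(data)),
    class = "combFitBayes")
}

#' @export
print.combFitBayes <- function(x, digits = 4, ...) {
  cat("Bayesian fit (MCMC): ", variantName(x$spec), " model\n", sep = "")
  cat("  ", x$n_obs, " observations, ", x$n_subjects, " subjects; ",
      x$config$n_chains, " chains x ", x$config$n_iter, " iterations (",
      x$config$burn_in, " burn-in, thin ", x$config$thin, ")\n", sep = "")
  tab <- x$summaries
  tab$mean <- signif(tab$mean, digits)
  tab$sd <- signif(tab$sd, digits)
  tab$q2.5 <- signif(tab$q2.5, digits)
  tab$q97.5 <- signif(tab$q97.5, digits)
  tab$rhat <- round(tab$rhat, 3)
  print(tab, row.names = FALSE)
  print(x$dic)
  invisible(x)
}

#' Export posterior draws as a long CSV
#'
#' One column per reported parameter plus a chain-id column.
#'
#' @param fit a `combFitBayes`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDrawsCSV <- function(fit, path) {
  stopifnot(inherits(fit, "combFitBayes"))
  out <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    data.frame(chain = ch, fit$draws[[ch]], check.names = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
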