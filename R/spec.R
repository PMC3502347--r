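#' Model specification
#'
#' Selects one of the four model variants for a longitudinal binary outcome:
#' simple logistic, beta-overdispersed logistic ("beta-binomial"),
#' logistic-normal (normal random effects only), or the combined model (both
#' a beta observation effect and normal subject effects).
#'
#' @param fixed character vector of fixed-effect terms (covariate names and
#'   `"a:b"` interactions); an intercept is always included.
#' @param random random-effects structure: `"none"`, `"intercept"`, or
#'   `"slope"` (random intercept plus random slope on the time variable).
#' @param overdispersed logical; include the beta observation effect?
#' @param time name of the time variable used for the random slope (and for
#'   centering); required when `random = "slope"`.
#' @param time_center value subtracted from the time variable inside the model
#'   layer before it enters the fixed or random terms (e.g. 6 to center infant
#'   age at month six). The data file keeps the raw scale.
#' @return an object of class `modelSpec`.
#' @examples
#' modelSpec(c("time", "G"), random = "intercept", overdispersed = TRUE,
#'           time = "time")
#' @export
modelSpec <- function(fixed, random = c("none", "intercept", "slope"),
                      overdispersed = FALSE, time = NULL, time_center = 0) {
  random <- match.arg(random)
  stopifnot(is.character(fixed), length(fixed) >= 1L,
            is.logical(overdispersed), length(overdispersed) == 1L)
  if (random == "slope" && is.null(time)) {
    stop("random = 'slope' requires the name of the time variable")
  }
  structure(list(fixed = fixed, random = random,
                 overdispersed = overdispersed,
                 time = time, time_center = time_center),
            class = "modelSpec")
}

#' @rdname modelSpec
#' @param spec a `modelSpec`.
#' @return `nRanef()` the number of normal random effects (0, 1 or 2);
#'   `variantName()` one of `"logistic"`, `"beta-binomial"`,
#'   `"logistic-normal"`, `"combined"`.
#' @export
nRanef <- function(spec) switch(spec$random, none = 0L, intercept = 1L, slope = 2L)

#' @rdname modelSpec
#' @export
variantName <- function(spec) {
  if (nRanef(spec) == 0L) {
    if (spec$overdispersed) "beta-binomial" else "logistic"
  } else {
    if (spec$overdispersed) "combined" else "logistic-normal"
  }
}

#' @export
print.modelSpec <- function(x, ...) {
  cat("Model variant: ", variantName(x), "\n", sep = "")
  cat("  fixed terms: 1 + ", paste(x$fixed, collapse = " + "), "\n", sep = "")
  cat("  random: ", x$random,
      if (x$random == "slope") paste0(" (time = ", x$time, ")"), "\n", sep = "")
  cat("  beta overdispersion: ", x$overdispersed, "\n", sep = "")
  invisible(x)
}

#' Parameters of the combined model
#'
#' Bundles the fixed-effect coefficients, the random-effect standard
#' deviations and the beta-overdispersion ratio `const` = beta/alpha, under
#' which the beta effect has mean `1/(1 + const)`.  The intercept and slope
#' random effects are independent, `b_i ~ N(0, diag(d0^2, d1^2))`.  `alpha`
#' and `beta` pin down the full beta law and are used by the Bayesian fit and
#' the generator; the Bernoulli likelihood depends on them only through
#' `const`, so the ML fit estimates `const` alone.
#'
#' @param xi numeric vector of fixed-effect coefficients, intercept first.
#' @param d0,d1 non-negative random intercept / slope standard deviations.
#' @param const non-negative overdispersion ratio beta/alpha; 0 switches the
#'   beta effect off.
#' @param alpha,beta optional positive beta-distribution parameters; when
#'   given, `const` is taken as `beta/alpha`.
#' @return an object of class `combinedParams`.
#' @export
combinedParams <- function(xi, d0 = 0, d1 = 0, const = 0,
                           alpha = NULL, beta = NULL) {
  stopifnot(is.numeric(xi), length(xi) >= 1L, all(is.finite(xi)))
  if (!is.null(alpha) || !is.null(beta)) {
    if (is.null(alpha) || is.null(beta)) {
      stop("provide both 'alpha' and 'beta' or neither")
    }
    stopifnot(alpha > 0, beta > 0)
    const <- beta / alpha
  }
  stopifnot(d0 >= 0, d1 >= 0, const >= 0)
  structure(list(xi = xi, d0 = d0, d1 = d1, const = const,
                 alpha = alpha, beta = beta),
            class = "combinedParams")
}

#' @export
print.combinedParams <- function(x, ...) {
  cat("combinedParams:\n  xi: ", paste(signif(x$xi, 4), collapse = ", "),
      "\n  d0 = ", x$d0, "  d1 = ", x$d1, "  const = ", signif(x$const, 4),
      "\n", sep = "")
  if (!is.null(x$alpha)) {
    cat("  beta law: alpha = ", x$alpha, ", beta = ", x$beta, "\n", sep = "")
  }
  invisible(x)
}

# Design matrices for a spec: fixed-effect matrix X (with intercept), the
# centered time vector zt used by the random slope, and the subject index.
# Errors name any covariate referenced by the fixed terms but absent.
modelMatrices <- function(data, spec) {
  df <- as.data.frame(data)
  form <- stats::reformulate(spec$fixed, intercept = TRUE)
  need <- all.vars(form)
  missing_cov <- setdiff(need, names(df))
  if (length(missing_cov)) {
    stop("covariate(s) named in fixed terms but missing from data: ",
         paste(missing_cov, collapse = ", "))
  }
  if (!is.null(spec$time) && spec$time_center != 0) {
    if (!spec$time %in% names(df)) {
      stop("covariate(s) named in fixed terms but missing from data: ",
           spec$time)
    }
    df[[spec$time]] <- df[[spec$time]] - spec$time_center
  }
  X <- stats::model.matrix(form, df)
  zt <- if (nRanef(spec) == 2L) df[[spec$time]] else NULL
  list(X = X, zt = zt, subj = subjectIndex(data))
}

#' Prior specification for the Bayesian fit
#'
#' Diffuse zero-mean normal priors (precision `xi_prec`) on each fixed-effect
#' coefficient, Gamma(`tau_shape`, `tau_rate`) priors on each random-effect
#' precision, and box-uniform priors on the beta parameters with lower bounds
#' above 1 so the beta density stays unimodal and finite on (0, 1).
#'
#' @param xi_prec prior precision of each fixed-effect coefficient.
#' @param tau_shape,tau_rate Gamma prior on each random-effect precision.
#' @param alpha_range,beta_range length-2 uniform prior bounds for the beta
#'   parameters; both lower bounds must exceed 1.
#' @return an object of class `priorSpec`.
#' @export
priorSpec <- function(xi_prec = 1e-6, tau_shape = 0.001, tau_rate = 0.001,
                      alpha_range = c(3, 5), beta_range = c(1.1, 1.5)) {
  stopifnot(xi_prec > 0, tau_shape > 0, tau_rate > 0,
            length(alpha_range) == 2L, length(beta_range) == 2L,
            alpha_range[1] < alpha_range[2], beta_range[1] < beta_range[2])
  if (alpha_range[1] <= 1 || beta_range[1] <= 1) {
    stop("alpha_range and beta_range must have lower bounds > 1 ",
         "(unimodality restriction)")
  }
  structure(list(xi_prec = xi_prec, tau_shape = tau_shape,
                 tau_rate = tau_rate, alpha_range = alpha_range,
                 beta_range = beta_range),
            class = "priorSpec")
}

#' MCMC run configuration
#'
#' Defaults mirror the study protocol: 70,000 iterations for the combined
#' model, 50,000 for the other variants, 10,000 burn-in, two chains.  Passing
#' `n_iter = NULL` defers the choice until the variant is known.
#'
#' @param n_iter total iterations per chain (NULL = variant default).
#' @param burn_in iterations discarded from the front of each chain.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param seed integer seed making the run reproducible.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return an object of class `mcmcConfig`.
#' @export
mcmcConfig <- function(n_iter = NULL, burn_in = 10000L, n_chains = 2L,
                       seed = 1L, thin = 1L) {
  stopifnot(is.null(n_iter) || n_iter > burn_in, burn_in >= 0L,
            n_chains >= 1L, thin >= 1L)
  structure(list(n_iter = n_iter, burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "mcmcConfig")
}
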