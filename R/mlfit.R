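#' Maximum-likelihood fit of the combined model and its special cases
#'
#' Maximizes the marginal likelihood — beta observation effect integrated in
#' closed form, normal random effects by Gauss-Hermite quadrature — with a
#' quasi-Newton (BFGS) optimizer.  Random-effect SDs and the overdispersion
#' ratio `const` are optimized on the log scale to enforce positivity and
#' reported on the natural scale; standard errors come from the inverse
#' observed information (numerical Hessian on the natural scale) and p-values
#' from two-sided Wald z tests.  Estimates of `const` (or an SD) below 1e-8
#' are reported as boundary values (~0) with no Wald inference: a Wald test of
#' a variance-type parameter against a boundary null is conservative.
#'
#' @param data a [longData] object; both outcome values must be present.
#' @param spec a [modelSpec].
#' @param q Gauss-Hermite points per random-effect dimension (default 10,
#'   non-adaptive).
#' @param adaptive use per-subject adaptively recentered quadrature?
#' @param init optional [combinedParams] of starting values; by default the
#'   fixed effects start at the ordinary logistic fit, SDs at 1, `const` at 0.1.
#' @param max_iter,tol optimizer iteration cap and relative tolerance.
#' @return an object of class `combFitML` with components `spec`, `estimates`
#'   (a [combinedParams]), `se`, `p_values`, `minus2loglik`, `converged`,
#'   `n_subjects`, `n_obs`, `boundary`, and optimizer metadata.
#' @seealso [compareFits()], [coefTable()]
#' @export
fitML <- function(data, spec, q = 10L, adaptive = FALSE, init = NULL,
                  max_iter = 500L, tol = 1e-10) {
  y <- outcomes(data)
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: all responses are ", y[1],
         "; the model is not estimable")
  }
  eng <- .llEngine(data, spec)
  nre <- eng$nre
  rule <- if (nre > 0L) gaussHermiteRule(q, nre) else NULL
  p <- ncol(eng$X)

  # starting values: logistic IRLS for xi
  if (is.null(init)) {
    g0 <- suppressWarnings(stats::glm.fit(eng$X, y,
                                          family = stats::binomial()))
    xi0 <- g0$coefficients
    if (any(abs(xi0) > 15)) {
      warning("very large logistic starting values; possible separation")
    }
    init <- combinedParams(xi = xi0, d0 = if (nre >= 1L) 1 else 0,
                           d1 = if (nre == 2L) 1 else 0,
                           const = if (spec$overdispersed) 0.1 else 0)
  }

  unpack <- function(par) {
    xi <- par[seq_len(p)]
    k <- p
    d0 <- d1 <- const <- 0
    if (nre >= 1L) { d0 <- exp(par[k + 1L]); k <- k + 1L }
    if (nre == 2L) { d1 <- exp(par[k + 1L]); k <- k + 1L }
    if (spec$overdispersed) const <- exp(par[k + 1L])
    list(xi = xi, d0 = d0, d1 = d1, const = const)
  }
  par0 <- c(init$xi,
            if (nre >= 1L) log(max(init$d0, 1e-3)),
            if (nre == 2L) log(max(init$d1, 1e-3)),
            if (spec$overdispersed) log(max(init$const, 1e-4)))

  negll <- function(par) {
    th <- unpack(par)
    v <- tryCatch(
      -sum(.subjectMarginals(eng, th$xi, th$d0, th$d1, th$const, rule,
                             adaptive)),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  # box constraints keep the log-scale variance parameters in a
  # scientifically meaningful range; unconstrained Gauss-Hermite likelihoods
  # admit spurious degenerate optima as the random-effect SD grows without
  # bound (the discrete node mixture outfits any genuine normal)
  lower <- c(rep(-50, p),
             if (nre >= 1L) log(1e-4), if (nre == 2L) log(1e-4),
             if (spec$overdispersed) log(1e-8))
  upper <- c(rep(50, p),
             if (nre >= 1L) log(30), if (nre == 2L) log(30),
             if (spec$overdispersed) log(1e3))
  opt <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, factr = 1e4))
  # boundary polish: a small fitted const can mask the boundary optimum;
  # restart along const ~ 0 and keep the better solution
  if (spec$overdispersed) {
    kc <- length(opt$par)
    if (exp(opt$par[kc]) < 0.05) {
      par_b <- opt$par
      par_b[kc] <- log(1e-8)
      opt2 <- stats::optim(par_b, negll, method = "L-BFGS-B",
                           lower = lower, upper = upper,
                           control = list(maxit = max_iter, factr = 1e4))
      if (opt2$value < opt$value) opt <- opt2
    }
  }
  th <- unpack(opt$par)
  converged <- opt$convergence == 0L
  if (!converged) {
    warning("optimizer did not converge (code ", opt$convergence, "): ",
            if (is.null(opt$message)) "iteration limit" else opt$message)
  }

  # free natural-scale parameters (boundary SDs / const excluded from Wald)
  est <- c(th$xi,
           if (nre >= 1L) th$d0, if (nre == 2L) th$d1,
           if (spec$overdispersed) th$const)
  nm <- c(colnames(eng$X),
          if (nre >= 1L) "d0", if (nre == 2L) "d1",
          if (spec$overdispersed) "const")
  names(est) <- nm
  boundary <- stats::setNames(rep(FALSE, length(est)), nm)
  boundary[nm %in% c("d0", "d1", "const")] <- est[nm %in% c("d0", "d1", "const")] < 1e-8

  free <- which(!boundary)
  negll_nat <- function(v) {
    full <- est
    full[free] <- v
    negll_from_natural(full, nm, p, nre, spec, eng, rule, adaptive)
  }
  se <- stats::setNames(rep(NA_real_, length(est)), nm)
  H <- tryCatch(stats::optimHess(est[free], negll_nat), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      dv[dv < 0] <- NA_real_
      se[free] <- sqrt(dv)
    }
  }
  zval <- est / se
  pval <- 2 * stats::pnorm(-abs(zval))
  pval[boundary] <- NA_real_

  m2ll <- 2 * negll(opt$par)
  structure(list(
    spec = spec,
    estimates = combinedParams(xi = stats::setNames(th$xi, colnames(eng$X)),
                               d0 = th$d0, d1 = th$d1, const = th$const),
    se = se, p_values = pval, minus2loglik = m2ll,
    converged = converged, boundary = boundary,
    n_subjects = eng$N, n_obs = length(y),
    n_par = length(est), q = if (nre > 0L) as.integer(q) else NA_integer_,
    adaptive = adaptive,
    optim = list(counts = opt$counts, value = opt$value,
                 convergence = opt$convergence),
    data_fingerprint = .dataFingerprint(data)),
    class = "combFitML")
}

negll_from_natural <- function(full, nm, p, nre, spec, eng, rule, adaptive) {
  xi <- full[seq_len(p)]
  d0 <- if (nre >= 1L) full[["d0"]] else 0
  d1 <- if (nre == 2L) full[["d1"]] else 0
  cst <- if (spec$overdispersed) full[["const"]] else 0
  v <- tryCatch(
    -sum(.subjectMarginals(eng, xi, abs(d0), abs(d1), max(cst, 0), rule,
                           adaptive)),
    error = function(e) Inf)
  if (!is.finite(v)) 1e10 else v
}

.dataFingerprint <- function(data) {
  y <- outcomes(data)
  c(n_obs = nrow(data), n_subjects = nSubjects(data),
    y_sum = sum(y), y_check = sum(y * seq_along(y)) %% 1e9)
}

#' Coefficient table of an ML fit
#'
#' One row per parameter: Effect, Estimate, s.e., p, mirroring the standard
#' report layout; the -2 log-likelihood is attached as an attribute and shown
#' by the print method.  Write it out with [utils::write.csv()] for a
#' plain-text report.
#'
#' @param fit a `combFitML` object.
#' @return a data frame with columns `effect`, `estimate`, `se`, `p`.
#' @export
coefTable <- function(fit) {
  stopifnot(inherits(fit, "combFitML"))
  est <- c(fit$estimates$xi,
           if (nRanef(fit$spec) >= 1L) c(d0 = fit$estimates$d0),
           if (nRanef(fit$spec) == 2L) c(d1 = fit$estimates$d1),
           if (fit$spec$overdispersed) c(const = fit$estimates$const))
  out <- data.frame(effect = names(est), estimate = unname(est),
                    se = unname(fit$se), p = unname(fit$p_values),
                    row.names = NULL)
  attr(out, "minus2loglik") <- fit$minus2loglik
  attr(out, "variant") <- variantName(fit$spec)
  out
}

#' @export
print.combFitML <- function(x, digits = 4, ...) {
  cat("Maximum-likelihood fit: ", variantName(x$spec), " model\n", sep = "")
  cat("  ", x$n_obs, " observations, ", x$n_subjects, " subjects; ",
      if (!is.na(x$q)) paste0(x$q, "-point ",
                              if (x$adaptive) "adaptive " else "",
                              "Gauss-Hermite; ") else "",
      if (x$converged) "converged" else "NOT CONVERGED", "\n", sep = "")
  tab <- coefTable(x)
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$p <- signif(tab$p, 3)
  if (any(x$boundary)) {
    tab$note <- ifelse(x$boundary, "boundary (~0)", "")
  }
  print(tab, row.names = FALSE)
  cat("  -2 log-likelihood: ", format(x$minus2loglik, nsmall = 2), "\n", sep = "")
  if (any(names(x$se) == "const") && !x$boundary[["const"]]) {
    cat("  note: Wald tests of variance-type parameters against a boundary",
        "null are conservative\n")
  }
  invisible(x)
}

#' Compare maximum-likelihood fits of nested variants
#'
#' Tabulates -2 log-likelihood and parameter counts across fits of the same
#' dataset, plus the -2 log-likelihood drops for every nested pair (same
#' fixed terms; a variant nests another when its random structure and
#' overdispersion flag are componentwise no richer).  No automatic p-values
#' are attached: the interesting comparisons involve variance-type parameters
#' on the boundary, where the usual chi-squared reference is invalid.
#'
#' @param ... `combFitML` objects, or a single list of them.
#' @return an object of class `combFitComparison`: a list with `table` (one
#'   row per fit) and `nested_deltas` (one row per nested pair).
#' @export
compareFits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "combFitML")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "combFitML")))
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (length(fits) > 1L &&
      !all(vapply(fps[-1], identical, TRUE, fps[[1]]))) {
    stop("fits were not computed on the same dataset")
  }
  tab <- data.frame(
    variant = vapply(fits, function(f) variantName(f$spec), character(1)),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    minus2loglik = vapply(fits, `[[`, numeric(1), "minus2loglik"))
  rank_re <- function(s) match(s$random, c("none", "intercept", "slope"))
  nests <- function(a, b) {  # TRUE if fit a is nested in fit b
    identical(a$spec$fixed, b$spec$fixed) &&
      rank_re(a$spec) <= rank_re(b$spec) &&
      a$spec$overdispersed <= b$spec$overdispersed &&
      !(rank_re(a$spec) == rank_re(b$spec) &&
          a$spec$overdispersed == b$spec$overdispersed)
  }
  deltas <- NULL
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i != j && nests(fits[[i]], fits[[j]])) {
      deltas <- rbind(deltas, data.frame(
        reduced = tab$variant[i], richer = tab$variant[j],
        delta_m2ll = tab$minus2loglik[i] - tab$minus2loglik[j]))
    }
  }
  structure(list(table = tab, nested_deltas = deltas),
            class = "combFitComparison")
}

#' @export
print.combFitComparison <- function(x, ...) {
  cat("Model comparison (-2 log-likelihood):\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$nested_deltas)) {
    cat("Nested-pair likelihood drops:\n")
    print(x$nested_deltas, row.names = FALSE)
  }
  invisible(x)
}
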