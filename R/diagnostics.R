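#' Bernoulli-level mean and variance
#'
#' Sample mean and unbiased sample variance of the pooled 0/1 outcomes.  For
#' i.i.d. Bernoulli data the two are tied by `var = p(1-p)` (up to the n/(n-1)
#' factor), so agreement here says nothing about overdispersion; the
#' binomial-level comparison does.
#'
#' @param data a [longData].
#' @return named vector `mean`, `variance`.
#' @export
bernoulliMeanVariance <- function(data) {
  y <- outcomes(data)
  if (length(y) < 2L) stop("need at least 2 records")
  c(mean = mean(y), variance = stats::var(y))
}

#' Collapse to per-subject binomial counts
#'
#' @param data a [longData].
#' @return data frame with one row per subject: `id`, `z` (successes), `n`
#'   (occasions), plus the subject's time-constant covariates.
#' @export
binomialCollapse <- function(data) {
  subj <- subjectIndex(data)
  y <- outcomes(data)
  ids <- unique(subjectIds(data))
  out <- data.frame(id = ids,
                    z = drop(rowsum(y, subj)),
                    n = drop(rowsum(rep(1L, length(y)), subj)))
  for (v in .timeConstantCovariates(data)) {
    out[[v]] <- as.data.frame(data)[[v]][!duplicated(subj)]
  }
  out
}

# covariates whose value never varies within a subject
.timeConstantCovariates <- function(data) {
  subj <- subjectIndex(data)
  covs <- setdiff(covariateNames(data), attr(data, "time_col"))
  df <- as.data.frame(data)
  covs[vapply(covs, function(v) {
    x <- df[[v]]
    if (!is.numeric(x)) x <- as.integer(factor(x))
    all(tapply(x, subj, function(z) length(unique(z))) == 1L)
  }, logical(1))]
}

.collapsedGLM <- function(data, covariates = NULL) {
  cz <- binomialCollapse(data)
  if (is.null(covariates)) covariates <- .timeConstantCovariates(data)
  form <- if (length(covariates)) {
    stats::reformulate(covariates, response = "cbind(z, n - z)")
  } else {
    stats::as.formula("cbind(z, n - z) ~ 1")
  }
  fit <- stats::glm(form, family = stats::binomial(), data = cz)
  if (!fit$converged) stop("binomial GLM on the collapsed counts did not converge")
  fit
}

#' Deviance-ratio dispersion estimate
#'
#' Collapses the data to per-subject binomial counts, fits a binomial GLM
#' (logit link) on the chosen covariates, and returns residual deviance /
#' residual degrees of freedom.  Values well above 1 indicate overdispersion;
#' the estimator leans on asymptotics and can mislead when the expected
#' counts are small, which is why [phiQuasi()] is reported alongside.
#'
#' @param data a [longData].
#' @param covariates covariate names for the collapsed fit; default: all
#'   time-constant covariates (collapsing destroys time-varying structure).
#' @return scalar dispersion estimate.
#' @export
phiDeviance <- function(data, covariates = NULL) {
  fit <- .collapsedGLM(data, covariates)
  if (fit$df.residual == 0L) return(0)
  fit$deviance / fit$df.residual
}

#' Quasi-binomial (Pearson) dispersion estimate
#'
#' Same collapsed binomial fit as [phiDeviance()] (identical coefficients);
#' the dispersion is the Pearson statistic over the residual degrees of
#' freedom, the quasi-binomial moment estimator.
#'
#' @inheritParams phiDeviance
#' @return scalar dispersion estimate.
#' @export
phiQuasi <- function(data, covariates = NULL) {
  fit <- .collapsedGLM(data, covariates)
  if (fit$df.residual == 0L) return(0)
  sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
}

#' Exploratory overdispersion report
#'
#' The standard pre-modeling check: the Bernoulli-level mean/variance pair,
#' the binomial-level pair (mean success proportion, variance of the
#' per-subject success counts) against the independence benchmark
#' `n p (1-p)`, and the two dispersion estimates from the collapsed binomial
#' fit.
#'
#' @inheritParams phiDeviance
#' @return an object of class `dispersionReport`.
#' @export
dispersionReport <- function(data, covariates = NULL) {
  bm <- bernoulliMeanVariance(data)
  cz <- binomialCollapse(data)
  pbar <- mean(cz$z / cz$n)
  nbar <- mean(cz$n)
  structure(list(
    bernoulli_mean = unname(bm["mean"]),
    bernoulli_variance = unname(bm["variance"]),
    binomial_mean = pbar,
    binomial_variance = stats::var(cz$z),
    binomial_benchmark = nbar * pbar * (1 - pbar),
    phi_deviance = phiDeviance(data, covariates),
    phi_quasi = phiQuasi(data, covariates)),
    class = "dispersionReport")
}

#' @export
print.dispersionReport <- function(x, digits = 3, ...) {
  cat("Overdispersion diagnostics\n")
  cat(sprintf("  Bernoulli level: mean %.3f, variance %.3f (i.i.d. benchmark %.3f)\n",
              x$bernoulli_mean, x$bernoulli_variance,
              x$bernoulli_mean * (1 - x$bernoulli_mean)))
  cat(sprintf("  Binomial level:  mean proportion %.3f, variance of counts %.3f (benchmark %.3f)\n",
              x$binomial_mean, x$binomial_variance, x$binomial_benchmark))
  cat(sprintf("  Dispersion: deviance ratio %.3f, quasi-binomial %.3f\n",
              x$phi_deviance, x$phi_quasi))
  invisible(x)
}
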