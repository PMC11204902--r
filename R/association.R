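## Nested logistic models: null (covariates + PCs) vs full (+ PRS),
## Nagelkerke pseudo-R-squared differencing, PRS odds ratios with Wald CIs,
## and Bonferroni correction across scores.

MODEL_COVARIATES <- list(
  model1 = c("sex", "age", "weight", "t2dm"),
  model2 = c("sex", "age", "weight", "t2dm", "smoking", "sbp", "total_chol"))

#' Covariate sets of the two nested-model specifications
#'
#' \code{model1}: sex, age, weight, T2DM. \code{model2}: model1 plus
#' smoking, systolic blood pressure and total cholesterol (the conventional
#' clinical risk-chart covariates).
#'
#' @param name \code{"model1"} or \code{"model2"}.
#' @return character vector of covariate column names.
#' @export
modelCovariates <- function(name = c("model1", "model2")) {
  MODEL_COVARIATES[[match.arg(name)]]
}

#' Maximum-likelihood logistic regression
#'
#' Thin wrapper over iteratively reweighted least squares
#' (\code{stats::glm.fit}, binomial/logit) exposing the log-likelihood and
#' Wald standard errors from the observed information. Convergence is
#' relative deviance change below 1e-10 within 100 iterations; fits showing
#' fitted probabilities at 0/1 together with exploding coefficients
#' (separation) are flagged non-converged.
#'
#' @param y 0/1 response vector.
#' @param design numeric model matrix including the intercept column.
#' @return list with \code{coefficients}, \code{standard_errors},
#'   \code{log_likelihood}, \code{converged}, \code{n}, \code{fitted}.
#' @export
fitLogistic <- function(y, design) {
  design <- as.matrix(design)
  n <- length(y)
  if (n != nrow(design)) stop("y and design sizes differ")
  if (n < ncol(design)) stop("more parameters than observations")
  if (length(unique(y)) < 2) stop("constant response")
  fit <- suppressWarnings(
    glm.fit(design, y, family = binomial(),
            control = list(epsilon = 1e-10, maxit = 100)))
  p <- fit$fitted.values
  eps <- 1e-10
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  w <- p * (1 - p)
  info <- crossprod(design * w, design)
  se <- rep(NA_real_, ncol(design))
  ok_info <- TRUE
  cv <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(cv)) ok_info <- FALSE else se <- sqrt(diag(cv))
  boundary <- any(p > 1 - 1e-8 | p < 1e-8)
  separated <- boundary && any(abs(fit$coefficients) > 10,
                               na.rm = TRUE)
  conv <- isTRUE(fit$converged) && ok_info && !separated &&
    !anyNA(fit$coefficients)
  list(coefficients = fit$coefficients, standard_errors = se,
       log_likelihood = ll, converged = conv, n = n, fitted = p)
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell \code{1 - exp((2/n) * (ll0 - ll1))} rescaled by its maximum
#' \code{1 - exp((2/n) * ll0)} so the statistic attains 1 at a perfect fit.
#'
#' @param loglik_model log-likelihood of the fitted model.
#' @param loglik_null log-likelihood of the intercept-only model.
#' @param n number of observations.
#' @return Nagelkerke R-squared in [0, 1].
#' @export
nagelkerkeR2 <- function(loglik_model, loglik_null, n) {
  if (n <= 0) stop("n must be positive")
  if (loglik_null >= 0) stop("degenerate null log-likelihood")
  if (loglik_model < loglik_null - 1e-8)
    stop("model log-likelihood below null: fits are not nested MLEs")
  cs <- 1 - exp((2 / n) * (loglik_null - loglik_model))
  cs_max <- 1 - exp((2 / n) * loglik_null)
  min(1, max(0, cs / cs_max))
}

#' Incremental (adjusted) PRS R-squared
#'
#' Difference of the full-model and null-model pseudo-R-squared; the share
#' of case-control discrimination attributable to the score beyond the
#' covariates.
#'
#' @param r2_full,r2_null pseudo-R-squared of the model with / without PRS.
#' @return \code{r2_full - r2_null}.
#' @export
adjustedPrsR2 <- function(r2_full, r2_null) r2_full - r2_null

#' Evaluate one polygenic score under one nested-model specification
#'
#' Joins samples by id across the score, phenotype table and PC
#' coordinates (inner join), fits the null model (intercept + covariates +
#' PCs) and the full model (+ raw PRS), plus the intercept-only baseline,
#' and reports Nagelkerke R-squared of both models, their difference, and
#' the PRS Wald odds ratio, 95\% CI and p-value. The OR is computed on
#' both the raw-score and per-SD scales; \code{or_scale} picks the
#' headline.
#'
#' @param prs a \linkS4class{PRSVector}.
#' @param phenotypes phenotype \code{data.frame} (see
#'   \code{\link{readPhenotypes}}).
#' @param pcs optional \linkS4class{PCResult} or samples x k matrix of PC
#'   coordinates (rownames = sample ids); \code{NULL} for no PC adjustment.
#' @param model \code{"model1"} or \code{"model2"}.
#' @param n_pcs number of PC columns to include (default: all supplied,
#'   or the Tracy-Widom-selected count when \code{pcs} is a
#'   \linkS4class{PCResult}).
#' @param or_scale headline odds-ratio scale (default \code{"per_sd"}).
#' @return an \linkS4class{AssociationResult}.
#' @export
evaluatePRS <- function(prs, phenotypes, pcs = NULL,
                        model = c("model1", "model2"), n_pcs = NULL,
                        or_scale = c("per_sd", "raw")) {
  model <- match.arg(model)
  or_scale <- match.arg(or_scale)
  covars <- MODEL_COVARIATES[[model]]

  pcmat <- NULL
  if (!is.null(pcs)) {
    if (is(pcs, "PCResult")) {
      if (is.null(n_pcs)) n_pcs <- nSignificant(pcs)
      pcmat <- pcCoords(pcs)[, seq_len(min(n_pcs, ncol(pcCoords(pcs)))),
                             drop = FALSE]
    } else {
      pcmat <- as.matrix(pcs)
      if (!is.null(n_pcs))
        pcmat <- pcmat[, seq_len(min(n_pcs, ncol(pcmat))), drop = FALSE]
    }
    if (ncol(pcmat) == 0) pcmat <- NULL
  }

  ph <- phenotypes[stats::complete.cases(phenotypes[c("case_status",
                                                      covars)]), ,
                   drop = FALSE]
  ids <- intersect(names(prsValues(prs)), ph$sample_id)
  if (!is.null(pcmat)) ids <- intersect(ids, rownames(pcmat))
  if (length(ids) < length(ph$sample_id) || length(ids) <
      length(prsValues(prs)))
    message(sprintf("evaluatePRS[%s]: analysing %d samples after join",
                    pgsId(prs), length(ids)))
  if (length(ids) < 10) stop("too few overlapping samples")

  ph <- ph[match(ids, ph$sample_id), , drop = FALSE]
  y <- ph$case_status
  x_prs <- unname(prsValues(prs)[ids])
  X0 <- cbind(`(Intercept)` = 1, as.matrix(ph[covars]))
  if (!is.null(pcmat)) X0 <- cbind(X0, pcmat[ids, , drop = FALSE])
  X1 <- cbind(X0, PRS = x_prs)

  f_int <- fitLogistic(y, matrix(1, length(y), 1))
  f0 <- fitLogistic(y, X0)
  f1 <- fitLogistic(y, X1)

  n <- length(y)
  conv <- f0$converged && f1$converged
  r2n <- nagelkerkeR2(f0$log_likelihood, f_int$log_likelihood, n)
  r2f <- nagelkerkeR2(max(f1$log_likelihood, f0$log_likelihood),
                      f_int$log_likelihood, n)
  b <- unname(f1$coefficients["PRS"])
  se <- unname(f1$standard_errors[length(f1$standard_errors)])
  s_prs <- sqrt(mean((x_prs - mean(x_prs))^2))
  zstat <- b / se
  pval <- 2 * pnorm(-abs(zstat))
  sc <- if (or_scale == "per_sd") s_prs else 1
  new("AssociationResult", pgsId = pgsId(prs), model = model,
      r2Null = r2n, r2Full = r2f,
      adjustedPrsR2 = adjustedPrsR2(r2f, r2n),
      orRaw = exp(b), orPerSd = exp(b * s_prs),
      ciLow = exp((b - 1.96 * se) * sc), ciHigh = exp((b + 1.96 * se) * sc),
      pValue = max(pval, .Machine$double.xmin), orScale = or_scale,
      bonferroniSignificant = NA, converged = conv, n = as.integer(n))
}

#' Bonferroni correction over a family of score tests
#'
#' @param p_values p-values in (0, 1].
#' @param alpha family-wise level (default 0.05).
#' @return list with \code{threshold} (\code{alpha / m}) and
#'   \code{significant} (logical, \code{p < threshold}).
#' @export
bonferroniAdjust <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0,1]")
  thr <- alpha / length(p_values)
  list(threshold = thr, significant = p_values < thr)
}

#' Apply Bonferroni flags to a list of AssociationResults
#'
#' @param results list of \linkS4class{AssociationResult} (one family).
#' @param alpha family-wise level.
#' @return the list with \code{bonferroniSignificant} filled in.
#' @export
flagBonferroni <- function(results, alpha = 0.05) {
  adj <- bonferroniAdjust(vapply(results, function(r) r@pValue, numeric(1)),
                          alpha = alpha)
  mapply(function(r, s) initialize(r, bonferroniSignificant = s),
         results, adj$significant, SIMPLIFY = FALSE)
}
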