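# Conditional logistic regression for 1:1 matched sets.
#
# For pairs the conditional likelihood reduces to intercept-free logistic
# regression on within-pair covariate differences Dx = x_case - x_control:
#   L(beta) = prod_i sigma(beta' Dx_i),  sigma(t) = 1/(1+exp(-t)).
# The log-likelihood is concave; Newton-Raphson with step-halving from
# beta = 0 converges in a handful of iterations on any non-separated fixture.

# Core optimizer on the difference matrix. Returns the MLE, observed-
# information SEs and convergence diagnostics.
clogit_diff_fit <- function(dx, tol = 1e-8, max_iter = 50L) {
  dx <- as.matrix(dx)
  p <- ncol(dx)
  if (nrow(dx) == 0L) stop("zero usable pairs")
  if (all(abs(dx) < .Machine$double.eps))
    return(list(beta = rep(NA_real_, p), se = rep(NA_real_, p),
                converged = FALSE, degenerate = TRUE, separated = FALSE,
                iter = 0L, loglik = nrow(dx) * log(0.5)))
  loglik <- function(b) sum(stats::plogis(drop(dx %*% b), log.p = TRUE))
  beta <- rep(0, p)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(dx %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(dx, 1 - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    info <- crossprod(dx * sqrt(w))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the concave log-likelihood increasing
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll <- ll_new
    if (iter >= max_iter || max(abs(beta)) > 25) break
  }
  # a numerically flat score at a huge beta is separation, not convergence
  if (converged && max(abs(beta)) > 15) converged <- FALSE
  separated <- !converged
  se <- rep(NA_real_, p)
  if (converged) {
    eta <- drop(dx %*% beta)
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    info <- crossprod(dx * sqrt(w))
    se <- sqrt(diag(solve(info)))
  }
  list(beta = beta, se = se, converged = converged, degenerate = FALSE,
       separated = separated, iter = iter, loglik = ll)
}

# Analytic conditional log-likelihood on a difference matrix; exported for
# grid cross-checks of the optimizer.
#' Conditional log-likelihood of a 1:1 matched design
#'
#' Evaluates \eqn{\sum_i \log \sigma(\beta' \Delta x_i)} for case-control
#' difference vectors \eqn{\Delta x_i}; useful as an independent oracle for
#' the optimizer (grid maximisation).
#'
#' @param beta coefficient vector.
#' @param dx matrix of case-minus-control differences (pairs x covariates).
#' @return Scalar log-likelihood.
#' @export
conditional_loglik <- function(beta, dx) {
  sum(stats::plogis(drop(as.matrix(dx) %*% beta), log.p = TRUE))
}

# Build the case-minus-control difference matrix for a set of model columns.
pair_differences <- function(dataset, columns, subset_pairs = NULL) {
  s <- dataset$samples
  ord <- order(s$pair_id, -s$case)
  s <- s[ord, ]
  z <- dataset$zmat[ord, , drop = FALSE]
  design <- matrix(NA_real_, nrow(s), length(columns),
                   dimnames = list(NULL, columns))
  for (cc in columns) {
    v <- if (cc %in% colnames(z)) z[, cc] else s[[cc]]
    if (is.null(v)) stop("model column not found: ", cc)
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    design[, cc] <- as.numeric(v)
  }
  idx_case <- seq(1L, nrow(s), by = 2L)
  dx <- design[idx_case, , drop = FALSE] - design[idx_case + 1L, , drop = FALSE]
  rownames(dx) <- s$pair_id[idx_case]
  if (!is.null(subset_pairs)) dx <- dx[rownames(dx) %in% subset_pairs, , drop = FALSE]
  dx[stats::complete.cases(dx), , drop = FALSE]
}

#' Fit a conditional logistic model to 1:1 matched pairs
#'
#' Maximises the exact 1:1 conditional likelihood
#' \eqn{\prod_i [1 + \exp(-\beta'\Delta x_i)]^{-1}} over case-minus-control
#' difference vectors by Newton-Raphson with step-halving, reporting the
#' Wald odds ratio per 1 SD of the (z-scored) exposure with its standard
#' error, 95 percent confidence interval and two-sided p-value.  Pairs with
#' any missing modelled variable are dropped (complete case).  Degenerate
#' designs (all differences zero) and separated designs are flagged rather
#' than silently reported.
#'
#' @param dataset a \code{\link{matched_dataset}}.
#' @param exposure metabolite id (column of the z-matrix) or covariate name.
#' @param covariates additional adjustment columns (z-matrix or sample
#'   columns); categorical covariates enter as integer codes.
#' @param model label recorded on the estimate (e.g. \code{"crude"},
#'   \code{"bmi_adjusted"}).
#' @param cohort label recorded on the estimate (default \code{"pooled"}).
#' @param subset_pairs optional vector of pair ids to restrict to.
#' @return A one-row data frame (class \code{risk_estimate}): metabolite,
#'   logor, se, or, ci_lo, ci_hi, p, n_pairs, model, cohort, converged,
#'   degenerate.
#' @export
fit_conditional_logistic <- function(dataset, exposure,
                                     covariates = character(0),
                                     model = "crude", cohort = "pooled",
                                     subset_pairs = NULL) {
  stopifnot(inherits(dataset, "matched_dataset"))
  dx <- pair_differences(dataset, c(exposure, covariates), subset_pairs)
  fit <- clogit_diff_fit(dx)
  b <- fit$beta[1L]; se <- fit$se[1L]
  est <- data.frame(
    metabolite = exposure,
    logor = b, se = se, or = exp(b),
    ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
    p = 2 * stats::pnorm(-abs(b / se)),
    n_pairs = nrow(dx), model = model, cohort = cohort,
    converged = fit$converged, degenerate = fit$degenerate,
    stringsAsFactors = FALSE)
  class(est) <- c("risk_estimate", "data.frame")
  est
}

# Covariate sets for the named adjustment models; columns must exist in the
# sample table (categoricals are coded by pair_differences).
model_covariates <- function(model) {
  switch(model,
    crude = character(0),
    bmi_adjusted = "bmi",
    fully_adjusted = c("bmi", "smoking", "pack_years", "alcohol", "hypertension"),
    fasting_adjusted = "fasting",
    stop("unknown model tag: ", model))
}

#' Metabolome-wide conditional-logistic scan
#'
#' Fits one conditional logistic model per metabolite, pooled over all pairs
#' and separately within each cohort (matching is within cohort, so pooling
#' is simply concatenation of strata).  Adjusted models are restricted to
#' pairs with complete risk-factor information.  Per-metabolite failures are
#' recorded and the scan continues.
#'
#' @param dataset a \code{\link{matched_dataset}}.
#' @param model adjustment tag; see \code{\link{fit_conditional_logistic}}.
#' @param metabolites columns of the z-matrix to scan (default all).
#' @param per_cohort also fit within each cohort (default TRUE).
#' @return Data frame of \code{risk_estimate} rows, one per metabolite x
#'   cohort (plus pooled).
#' @export
scan_metabolome <- function(dataset, model = "crude", metabolites = NULL,
                            per_cohort = TRUE) {
  stopifnot(inherits(dataset, "matched_dataset"))
  if (is.null(metabolites)) metabolites <- colnames(dataset$zmat)
  covars <- model_covariates(model)
  cohorts <- if (per_cohort) unique(dataset$samples$cohort) else character(0)
  pair_cohort <- tapply(dataset$samples$cohort, dataset$samples$pair_id,
                        function(v) v[1L])
  res <- vector("list", length(metabolites) * (1L + length(cohorts)))
  k <- 0L
  for (m in metabolites) {
    for (co in c("pooled", cohorts)) {
      sp <- if (co == "pooled") NULL else names(pair_cohort)[pair_cohort == co]
      k <- k + 1L
      res[[k]] <- tryCatch(
        fit_conditional_logistic(dataset, m, covars, model, co, sp),
        error = function(e) {
          data.frame(metabolite = m, logor = NA_real_, se = NA_real_,
                     or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     p = NA_real_, n_pairs = 0L, model = model, cohort = co,
                     converged = FALSE, degenerate = TRUE,
                     stringsAsFactors = FALSE)
        })
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cochran's Q heterogeneity across stratum estimates
#'
#' \eqn{Q = \sum_k w_k (\beta_k - \bar\beta)^2} with inverse-variance
#' weights \eqn{w_k = 1/SE_k^2} and
#' \eqn{\bar\beta = \sum w_k \beta_k / \sum w_k}; p from a chi-square with
#' K - 1 degrees of freedom.
#'
#' @param beta,se stratum estimates and standard errors.
#' @return List with \code{Q}, \code{df}, \code{p} and the pooled
#'   \code{beta_bar}.
#' @export
cochran_q <- function(beta, se) {
  keep <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[keep]; se <- se[keep]
  k <- length(beta)
  if (k < 2L) return(list(Q = NA_real_, df = NA_integer_, p = NA_real_,
                          beta_bar = if (k) beta else NA_real_))
  w <- 1 / se^2
  bb <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bb)^2)
  list(Q = q, df = k - 1L, p = stats::pchisq(q, k - 1L, lower.tail = FALSE),
       beta_bar = bb)
}

#' Stratified conditional-logistic analysis with heterogeneity test
#'
#' Pairs are assigned to strata by the case's value of the stratifier
#' (matching variables are shared within a pair; non-matching covariates
#' differ, and the case's value is the conventional anchor).  Continuous
#' stratifiers are cut at the pooled median.  A conditional logistic model
#' is fitted per stratum and between-stratum heterogeneity assessed by
#' Cochran's Q; strata with fewer than two informative pairs are excluded
#' from Q with a warning.
#'
#' @param dataset a \code{\link{matched_dataset}}.
#' @param stratifier sample-table column to stratify on.
#' @param exposure metabolite id or covariate to estimate.
#' @param covariates optional adjustment columns.
#' @return List with \code{estimates} (per-stratum risk_estimate rows) and
#'   \code{heterogeneity} (\code{\link{cochran_q}} output).
#' @export
stratified_analysis <- function(dataset, stratifier, exposure,
                                covariates = character(0)) {
  s <- dataset$samples
  v <- s[[stratifier]]
  if (is.null(v)) stop("stratifier not found: ", stratifier)
  cases <- s[s$case == 1L, ]
  sv <- cases[[stratifier]]
  if (is.numeric(sv)) {
    cut_at <- stats::median(sv, na.rm = TRUE)
    stratum <- ifelse(sv <= cut_at, paste0("<=", signif(cut_at, 3)),
                      paste0(">", signif(cut_at, 3)))
  } else stratum <- as.character(sv)
  names(stratum) <- cases$pair_id
  ests <- lapply(sort(unique(stratum)), function(st) {
    sp <- names(stratum)[stratum == st]
    tryCatch({
      e <- fit_conditional_logistic(dataset, exposure, covariates,
                                    model = "crude", cohort = st,
                                    subset_pairs = sp)
      e$stratum <- st
      e
    }, error = function(err) NULL)
  })
  ests <- do.call(rbind, ests)
  informative <- is.finite(ests$logor) & is.finite(ests$se) & ests$n_pairs >= 2L
  if (any(!informative))
    warning("stratum excluded from heterogeneity test: ",
            paste(ests$stratum[!informative], collapse = ", "))
  het <- cochran_q(ests$logor[informative], ests$se[informative])
  list(estimates = ests, heterogeneity = het)
}
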