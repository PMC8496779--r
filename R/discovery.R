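#' Effective number of independent tests from principal components
#'
#' Metabolite panels are strongly correlated, so a Bonferroni correction on
#' the raw column count is too severe.  The effective number of tests (ENT)
#' is the number of principal components needed to explain more than 95
#' percent (by default) of the variance of the metabolite matrix: the
#' eigenvalues of the sample correlation matrix are accumulated and ENT is
#' the smallest k whose cumulative fraction exceeds \code{var_frac}
#' (strictly; the equal-eigenvalue boundary therefore requires all
#' components).
#'
#' @param z complete (imputed) z-scored matrix, samples x metabolites.
#' @param var_frac variance fraction to exceed (default 0.95).
#' @return Integer ENT.
#' @export
effective_tests <- function(z, var_frac = 0.95) {
  stopifnot(is.matrix(z))
  if (anyNA(z)) stop("z-matrix contains missing cells; impute first")
  cm <- stats::cor(z)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0  # numerical negatives from near-singular panels
  frac <- cumsum(ev) / sum(ev)
  ent <- which(frac > var_frac)[1L]
  if (is.na(ent)) ent <- length(ev)
  as.integer(ent)
}

#' Bonferroni-style significance threshold from the ENT
#'
#' @param ent effective number of tests (>= 1).
#' @return 0.05 / ENT at full precision (display rounding is the caller's
#'   concern).
#' @export
significance_threshold <- function(ent) {
  if (!is.finite(ent) || ent < 1) stop("ENT must be >= 1")
  0.05 / ent
}

#' Flag robustly associated metabolites
#'
#' A metabolite is deemed robustly associated when its pooled p-value is at
#' or below the ENT-corrected threshold AND it is nominally significant
#' (p <= 0.05) in at least two cohorts independently; both comparisons are
#' boundary-inclusive.  Cohorts with missing estimates count as
#' non-significant.
#'
#' @param pooled data frame with columns \code{metabolite} and \code{p}
#'   (pooled analysis).
#' @param cohort_p matrix or data frame of per-cohort p-values with rownames
#'   (or a \code{metabolite} column) aligned to the pooled metabolites;
#'   columns are cohorts.
#' @param threshold the ENT-corrected pooled threshold
#'   (\code{\link{significance_threshold}}).
#' @param alpha_cohort nominal per-cohort level (default 0.05).
#' @param min_cohorts cohorts required at the nominal level (default 2).
#' @return A \code{discovery_result} list: the per-metabolite table with the
#'   \code{robust} flag, the threshold and the counts.
#' @export
robust_hits <- function(pooled, cohort_p, threshold,
                        alpha_cohort = 0.05, min_cohorts = 2L) {
  stopifnot(all(c("metabolite", "p") %in% names(pooled)))
  if (is.data.frame(cohort_p)) {
    if ("metabolite" %in% names(cohort_p)) {
      rownames(cohort_p) <- cohort_p$metabolite
      cohort_p$metabolite <- NULL
    }
    cohort_p <- as.matrix(cohort_p)
  }
  cp <- cohort_p[match(pooled$metabolite, rownames(cohort_p)), , drop = FALSE]
  n_nominal <- rowSums(cp <= alpha_cohort, na.rm = TRUE)
  robust <- !is.na(pooled$p) & pooled$p <= threshold & n_nominal >= min_cohorts
  tab <- data.frame(metabolite = pooled$metabolite, p_pooled = pooled$p,
                    n_cohorts_nominal = as.integer(n_nominal),
                    robust = robust, stringsAsFactors = FALSE)
  structure(list(table = tab, threshold = threshold,
                 alpha_cohort = alpha_cohort, min_cohorts = min_cohorts,
                 n_robust = sum(robust)),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("discovery_result:", x$n_robust, "robust hit(s) of",
      nrow(x$table), "metabolites at pooled threshold",
      signif(x$threshold, 3), "\n")
  invisible(x)
}
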