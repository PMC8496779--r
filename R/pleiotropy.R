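#' Variance in a standardized trait explained by one SNP
#'
#' Under Hardy-Weinberg equilibrium a biallelic SNP with effect-allele
#' frequency f and per-allele effect beta (trait in SD units) explains
#' \eqn{r^2 = 2 f (1-f) \beta^2} of the trait variance.  When the EAF is
#' unavailable the fallback \eqn{r^2 = z^2 / n} (with z = beta/se) may be
#' used instead via \code{snp_r2_from_z}.
#'
#' @param beta per-allele effect in SD units (vectorised).
#' @param eaf effect-allele frequency in (0, 1).
#' @return Variance fraction(s).
#' @export
snp_r2 <- function(beta, eaf) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1))
    stop("eaf must lie in (0, 1)")
  2 * eaf * (1 - eaf) * beta^2
}

#' @rdname snp_r2
#' @param se,n standard error and sample size for the z-based fallback.
#' @export
snp_r2_from_z <- function(beta, se, n) (beta / se)^2 / n

#' Instrument-specificity profile for a candidate metabolite
#'
#' For a candidate risk metabolite and its genetic instruments, computes the
#' cumulative variance explained \eqn{\sum_j 2 f_j (1-f_j) \beta_j^2} in
#' every metabolite of a GWAS panel, ranks the candidate among them
#' (1 = most variance explained), and flags the instrument set as
#' pleiotropic when any other metabolite's cumulative R-squared matches or
#' exceeds the candidate's — i.e. the candidate is not uniquely rank 1, so
#' a causal interpretation specific to the candidate is not supported.
#'
#' @param instruments data frame of the candidate's instruments (needs
#'   \code{snp}).
#' @param panel named list of GWAS summary data frames (one per metabolite,
#'   with \code{snp}, \code{beta}, \code{eaf}).
#' @param candidate name of the candidate metabolite (must appear in
#'   \code{panel}).
#' @return A \code{specificity_profile} list: the per-metabolite cumulative
#'   R-squared table, the candidate's rank, the ratio of the candidate's
#'   R-squared to the best other metabolite's, the pleiotropic flag, and
#'   any instruments missing from a panel table (they contribute 0).
#' @export
specificity_profile <- function(instruments, panel, candidate) {
  stopifnot(is.list(panel), candidate %in% names(panel))
  snps <- unique(instruments$snp)
  if (length(snps) == 0L) stop("empty instrument set")
  missing_log <- list()
  r2 <- vapply(names(panel), function(m) {
    g <- panel[[m]]
    idx <- match(snps, g$snp)
    absent <- snps[is.na(idx)]
    if (length(absent)) missing_log[[m]] <<- absent
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(0)
    sum(snp_r2(g$beta[idx], g$eaf[idx]))
  }, numeric(1))
  ord <- order(r2, decreasing = TRUE)
  rank_tab <- data.frame(metabolite = names(panel)[ord],
                         cumulative_r2 = r2[ord],
                         rank = rank(-r2, ties.method = "min")[ord],
                         stringsAsFactors = FALSE)
  cand_r2 <- r2[[candidate]]
  best_other <- max(r2[names(r2) != candidate])
  pleiotropic <- best_other >= cand_r2
  structure(list(candidate = candidate, table = rank_tab,
                 candidate_r2 = cand_r2,
                 candidate_rank = rank_tab$rank[rank_tab$metabolite == candidate],
                 specificity_ratio = cand_r2 / best_other,
                 pleiotropic = pleiotropic,
                 missing_snps = missing_log),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat("specificity_profile for", x$candidate, "\n",
      " rank", x$candidate_rank, "of", nrow(x$table),
      "| R2", signif(x$candidate_r2, 3),
      "| ratio to best other", signif(x$specificity_ratio, 3),
      "| pleiotropic:", x$pleiotropic, "\n")
  invisible(x)
}
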