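#' Standardize an effect profile to z-scores
#'
#' Divides each effect estimate by its standard error, producing the
#' standardized profile used for cross-analysis correlations.  Risk
#' estimates enter on the log odds-ratio scale, never as odds ratios.  Rows
#' with non-positive SE are dropped with a warning.
#'
#' @param estimates data frame with columns \code{metabolite},
#'   \code{estimate} and \code{se}.  Risk-scan output
#'   (\code{\link{scan_metabolome}}) and MR-scan output
#'   (\code{\link{mr_scan}}) are accepted directly and mapped onto these
#'   columns.
#' @param source profile tag: \code{"risk"}, \code{"mr_bmi"} or
#'   \code{"mr_negative_control"} (free-form allowed).
#' @return An \code{effect_profile} data frame: \code{metabolite}, \code{z},
#'   \code{source}.
#' @export
standardized_profile <- function(estimates, source = "risk") {
  df <- as.data.frame(estimates)
  if (!"estimate" %in% names(df)) {
    if ("logor" %in% names(df)) df$estimate <- df$logor
    else if ("beta" %in% names(df)) df$estimate <- df$beta
  }
  stopifnot(all(c("metabolite", "estimate", "se") %in% names(df)))
  bad <- !is.finite(df$se) | df$se <= 0 | !is.finite(df$estimate)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive or missing SE dropped")
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$metabolite)) stop("duplicate metabolite ids in profile")
  out <- data.frame(metabolite = df$metabolite, z = df$estimate / df$se,
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("effect_profile", "data.frame")
  out
}

# Spearman rho on average ranks with the two-sided t approximation
# (exact permutation available for small profiles).
spearman_t <- function(x, y, exact_permutation = FALSE) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (exact_permutation && n <= 10L) {
    perms <- permute_all(n)
    rx <- rank(x)
    stat0 <- abs(stats::cor(rx, rank(y)))
    stats_p <- apply(perms, 1L, function(idx) abs(stats::cor(rx, rank(y)[idx])))
    p <- mean(stats_p >= stat0 - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

permute_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permute_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman correlation between two effect profiles
#'
#' Intersects the two profiles by metabolite id and correlates their
#' standardized effects by Spearman rank correlation (average ranks for
#' ties; two-sided p from the t approximation, or an exact permutation test
#' for 10 or fewer metabolites when requested).  Platforms should never be
#' mixed in one correlation: compute per platform and report both.
#'
#' @param profile_a,profile_b \code{effect_profile} data frames
#'   (\code{\link{standardized_profile}}).
#' @param exact_permutation use the exact permutation p for n <= 10.
#' @return List: \code{rho}, \code{p}, \code{n_common}, \code{sources}.
#' @export
profile_correlation <- function(profile_a, profile_b,
                                exact_permutation = FALSE) {
  common <- intersect(profile_a$metabolite, profile_b$metabolite)
  if (length(common) < 3L)
    stop("fewer than 3 metabolites in common")
  za <- profile_a$z[match(common, profile_a$metabolite)]
  zb <- profile_b$z[match(common, profile_b$metabolite)]
  st <- spearman_t(za, zb, exact_permutation)
  list(rho = st$rho, p = st$p, n_common = st$n,
       sources = c(unique(profile_a$source)[1], unique(profile_b$source)[1]))
}

#' Negative-control comparison of a risk profile with a null-exposure scan
#'
#' Correlates the observational risk profile with the MR profile of a
#' negative-control exposure (one with no plausible effect on the outcome,
#' used to calibrate null behaviour), and reports how many of the
#' risk-robust metabolites are nonetheless flagged MR-significant under the
#' null exposure — a count expected to be approximately zero in a
#' well-calibrated analysis.
#'
#' @param risk_profile \code{effect_profile} of the risk scan.
#' @param null_scan output of \code{\link{mr_scan}} for the negative-control
#'   exposure.
#' @param robust_ids metabolite ids deemed robustly risk-associated.
#' @return List: the correlation (\code{rho}, \code{p}, \code{n_common}) and
#'   the overlap report (\code{n_robust}, \code{n_robust_mr_significant},
#'   their ids).
#' @export
negative_control_comparison <- function(risk_profile, null_scan, robust_ids) {
  ivw <- null_scan[null_scan$method == "IVW", , drop = FALSE]
  null_profile <- standardized_profile(ivw, source = "mr_negative_control")
  corr <- profile_correlation(risk_profile, null_profile)
  flagged <- ivw$metabolite[ivw$significant]
  overlap <- intersect(robust_ids, flagged)
  c(corr, list(n_robust = length(robust_ids),
               n_robust_mr_significant = length(overlap),
               robust_mr_significant = overlap))
}
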