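# Two-sample Mendelian randomisation: instrument selection, allele
# harmonisation and the IVW / MR-Egger / weighted-median estimator family.

#' Select and LD-prune genetic instruments
#'
#' Filters exposure summary statistics at a significance threshold and
#' greedily prunes for linkage disequilibrium: SNPs are visited in order of
#' ascending p-value and retained only if their R-squared with every
#' already-retained SNP is below \code{r2_thresh}.  Without an LD matrix all
#' p-passing SNPs are treated as independent (as published instrument lists
#' are), which is recorded in the provenance.
#'
#' @param exposure GWAS summary data frame (\code{snp, effect_allele,
#'   other_allele, eaf, beta, se, pval, n}).
#' @param p_thresh genome-wide significance threshold (default 5e-8).
#' @param r2_thresh pairwise LD bound among retained SNPs (default 0.01).
#' @param ld optional symmetric R-squared matrix with SNP dimnames.
#' @return The retained rows, with a \code{provenance} attribute recording
#'   thresholds and per-SNP drop reasons.
#' @export
select_instruments <- function(exposure, p_thresh = 5e-8, r2_thresh = 0.01,
                               ld = NULL) {
  stopifnot(all(c("snp", "pval") %in% names(exposure)))
  drops <- character(0)
  pass <- exposure[exposure$pval < p_thresh, , drop = FALSE]
  if (nrow(exposure) > nrow(pass))
    drops <- stats::setNames(rep("p >= threshold", nrow(exposure) - nrow(pass)),
                             setdiff(exposure$snp, pass$snp))
  if (nrow(pass) == 0L) stop("no instruments pass the p-value threshold")
  pass <- pass[order(pass$pval), , drop = FALSE]
  if (!is.null(ld)) {
    kept <- character(0)
    for (s in pass$snp) {
      r2 <- if (length(kept)) ld[s, kept] else numeric(0)
      if (all(r2 < r2_thresh)) kept <- c(kept, s)
      else drops[s] <- "LD with retained instrument"
    }
    pass <- pass[pass$snp %in% kept, , drop = FALSE]
    ld_note <- "greedy pruning on supplied LD matrix"
  } else ld_note <- "no LD matrix supplied; p-passing set assumed pre-pruned"
  if (nrow(pass) == 0L) stop("no instruments survive LD pruning")
  attr(pass, "provenance") <- list(p_thresh = p_thresh, r2_thresh = r2_thresh,
                                   ld = ld_note, drops = drops)
  pass
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

flip_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the outcome table to the exposure's effect alleles.  Outcome rows
#' whose effect allele equals the exposure's other allele have their beta
#' sign flipped and EAF complemented; strand flips (complementary allele
#' pairs) are resolved the same way.  Palindromic SNPs (A/T or C/G) whose
#' EAF falls inside the ambiguity window on either side are dropped, as are
#' unresolvable allele mismatches; every drop is logged with its reason.
#'
#' @param exposure,outcome GWAS summary data frames sharing \code{snp} ids.
#' @param palindromic_window EAF interval in which a palindromic SNP's
#'   strand cannot be called (default [0.42, 0.58]).
#' @return An \code{instrument_set} data frame: per SNP
#'   \code{beta_exposure, se_exposure, beta_outcome, se_outcome, eaf}, with
#'   a \code{drops} attribute naming removed SNPs and reasons.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  common <- intersect(exposure$snp, outcome$snp)
  drops <- character(0)
  ex <- exposure[match(common, exposure$snp), ]
  ou <- outcome[match(common, outcome$snp), ]
  keep <- rep(TRUE, length(common))
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  for (i in seq_along(common)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      amb <- function(f) f >= palindromic_window[1] & f <= palindromic_window[2]
      if (amb(ex$eaf[i]) || amb(ou$eaf[i])) {
        keep[i] <- FALSE
        drops[common[i]] <- "palindromic with ambiguous EAF"
        next
      }
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      # aligned
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else if (!pal && ea_y == flip_allele(ea_x) && oa_y == flip_allele(oa_x)) {
      # strand flip, same orientation
    } else if (!pal && ea_y == flip_allele(oa_x) && oa_y == flip_allele(ea_x)) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else if (pal && ea_y %in% c(ea_x, oa_x)) {
      # palindromic outside the ambiguity window: align by frequency
      if ((ou$eaf[i] > 0.5) != (ex$eaf[i] > 0.5)) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else {
      keep[i] <- FALSE
      drops[common[i]] <- "allele mismatch"
    }
  }
  res <- data.frame(snp = common,
                    beta_exposure = ex$beta, se_exposure = ex$se,
                    beta_outcome = beta_out, se_outcome = ou$se,
                    eaf = ex$eaf, stringsAsFactors = FALSE)[keep, ]
  if (nrow(res) == 0L) stop("no SNPs survive harmonisation")
  rownames(res) <- NULL
  class(res) <- c("instrument_set", "data.frame")
  attr(res, "drops") <- drops
  res
}

mr_result <- function(method, beta, se, n_snps, Q = NA_real_,
                      egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                      note = NA_character_) {
  data.frame(method = method, beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(beta / se)),
             egger_intercept = egger_intercept,
             egger_intercept_se = egger_intercept_se,
             Q = Q, n_snps = n_snps, note = note, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin: \eqn{\hat\beta = \sum w_j \beta_{Xj}\beta_{Yj} / \sum w_j
#' \beta_{Xj}^2} with \eqn{w_j = 1/se_{Yj}^2}.  The SE,
#' \eqn{\sqrt{1/\sum w_j \beta_{Xj}^2}}, is inflated by
#' \eqn{\sqrt{Q/(J-1)}} when Cochran's Q exceeds its degrees of freedom
#' (multiplicative random-effects model).  A single SNP yields the Wald
#' ratio with a first-order delta-method SE, flagged in the output.
#'
#' @param instruments an \code{\link{instrument_set}}.
#' @return One-row data frame: method, beta, se, p, Q, n_snps.
#' @export
mr_ivw <- function(instruments) {
  j <- nrow(instruments)
  if (j < 1L) stop("at least one instrument required")
  bx <- instruments$beta_exposure; by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  if (j == 1L) {
    beta <- by / bx
    se <- abs(sy / bx)
    return(mr_result("IVW", beta, se, 1L, note = "single-SNP Wald ratio"))
  }
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  if (q > (j - 1)) se <- se * sqrt(q / (j - 1))
  mr_result("IVW", beta, se, j, Q = q)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept (weights \eqn{1/se_Y^2}); the slope is the pleiotropy-adjusted
#' causal estimate and the intercept estimates average directional
#' pleiotropy.  Exposure betas are oriented positive first (flipping the
#' sign of both betas where needed), as the method requires.  SEs carry the
#' same multiplicative overdispersion inflation as the IVW fit, with J - 2
#' degrees of freedom.
#'
#' @param instruments an \code{\link{instrument_set}} with >= 3 SNPs.
#' @return One-row data frame with slope, intercept and their SEs.
#' @export
mr_egger <- function(instruments) {
  j <- nrow(instruments)
  if (j < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- instruments$beta_exposure < 0
  bx <- abs(instruments$beta_exposure)
  by <- ifelse(flip, -instruments$beta_outcome, instruments$beta_outcome)
  sy <- instruments$se_outcome
  w <- 1 / sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  coefs <- stats::coef(fit)
  resid_q <- sum(w * stats::residuals(fit)^2)
  # fixed-effect covariance (X'WX)^-1, then multiplicative overdispersion
  xmat <- cbind(1, bx)
  se_fixed <- sqrt(diag(solve(crossprod(xmat * sqrt(w)))))
  se <- se_fixed * sqrt(max(1, resid_q / (j - 2)))
  mr_result("Egger", unname(coefs["bx"]), se[2L], j, Q = resid_q,
            egger_intercept = unname(coefs["(Intercept)"]),
            egger_intercept_se = se[1L])
}

#' Weighted-median MR estimate
#'
#' Orders the per-SNP Wald ratios \eqn{\theta_j = \beta_{Yj}/\beta_{Xj}}
#' and returns the value at 50 percent of cumulative inverse-variance
#' weight (delta-method weights \eqn{\beta_{Xj}^2/se_{Yj}^2}, normalised),
#' interpolating linearly between the weight midpoints
#' \eqn{s_k = \sum_{1}^{k} w_j - w_k/2}.  Consistent when at least half the
#' weight comes from valid instruments.  The SE is the SD of the estimate
#' over parametric bootstrap resamples of both beta vectors from their
#' stated SEs.
#'
#' @param instruments an \code{\link{instrument_set}} with >= 3 SNPs.
#' @param n_boot bootstrap resamples for the SE (default 1000).
#' @param seed RNG seed making the bootstrap reproducible.
#' @return One-row data frame: method, beta, se, p, n_snps.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure beta dropped")
    instruments <- instruments[!zero, , drop = FALSE]
  }
  j <- nrow(instruments)
  if (j < 3L) stop("weighted median requires at least 3 instruments")
  wm <- function(bx, by, sy) {
    theta <- by / bx
    w <- bx^2 / sy^2
    ord <- order(theta)
    theta <- theta[ord]; w <- w[ord] / sum(w)
    s <- cumsum(w) - w / 2
    if (0.5 <= s[1L]) return(theta[1L])
    if (0.5 >= s[length(s)]) return(theta[length(s)])
    stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
  }
  est <- wm(instruments$beta_exposure, instruments$beta_outcome,
            instruments$se_outcome)
  set.seed(seed)
  boots <- replicate(n_boot, {
    bx <- stats::rnorm(j, instruments$beta_exposure, instruments$se_exposure)
    by <- stats::rnorm(j, instruments$beta_outcome, instruments$se_outcome)
    wm(bx, by, instruments$se_outcome)
  })
  mr_result("weighted_median", est, stats::sd(boots), j)
}

#' Panel-wide MR scan of one exposure against every metabolite
#'
#' Runs instrument selection once on the exposure, then per metabolite:
#' harmonisation and all three estimators.  A metabolite is flagged when its
#' IVW p-value falls below its platform's ENT-corrected threshold.
#' Per-metabolite failures are logged and the scan continues.
#'
#' @param exposure exposure GWAS summary data frame.
#' @param outcome_panel named list of outcome GWAS data frames, one per
#'   metabolite.
#' @param threshold significance threshold(s): a single value or a named
#'   vector/list per metabolite (e.g. per platform).
#' @param p_thresh,r2_thresh,ld passed to \code{\link{select_instruments}}.
#' @param n_boot,seed passed to \code{\link{mr_weighted_median}}.
#' @return Data frame with one row per metabolite x method plus the
#'   \code{significant} flag (IVW row), and a \code{failures} attribute.
#' @export
mr_scan <- function(exposure, outcome_panel, threshold = 0.05,
                    p_thresh = 5e-8, r2_thresh = 0.01, ld = NULL,
                    n_boot = 200L, seed = 1L) {
  stopifnot(is.list(outcome_panel), length(outcome_panel) >= 1L,
            !is.null(names(outcome_panel)))
  ins_exp <- select_instruments(exposure, p_thresh, r2_thresh, ld)
  thr <- if (length(threshold) == 1L)
    stats::setNames(rep(as.numeric(threshold), length(outcome_panel)),
                    names(outcome_panel))
  else unlist(threshold)[names(outcome_panel)]
  failures <- character(0)
  rows <- lapply(names(outcome_panel), function(m) {
    tryCatch({
      ins <- harmonize(ins_exp, outcome_panel[[m]])
      ests <- rbind(mr_ivw(ins),
                    if (nrow(ins) >= 3L) mr_egger(ins),
                    if (nrow(ins) >= 3L)
                      mr_weighted_median(ins, n_boot, seed))
      ests$metabolite <- m
      ests$significant <- ests$method == "IVW" & ests$p < thr[m]
      ests
    }, error = function(e) {
      failures[m] <<- conditionMessage(e)
      NULL
    })
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out <- out[, c("metabolite", setdiff(names(out), "metabolite"))]
    rownames(out) <- NULL
  }
  attr(out, "failures") <- failures
  out
}
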