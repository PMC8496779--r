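#' Configuration for the synthetic matched-cohort generator
#'
#' Collects every knob of the cohort simulator.  Log concentrations follow a
#' latent factor model; a standard-normal BMI covariate both shifts
#' metabolite levels (through \code{bmi_effect_on_metabolites}) and enters
#' disease risk (through \code{bmi_logor}), reproducing the confounding
#' structure that BMI adjustment is meant to remove.  Disease labels inside
#' each matched pair follow the conditional logistic model exactly, so the
#' fitted model is well specified and parameter recovery is a meaningful
#' check.
#'
#' @param n_pairs number of 1:1 matched case-control pairs (>= 1).
#' @param n_metabolites number of metabolite columns (>= 1).
#' @param n_cohorts number of cohorts the pairs are spread over.
#' @param n_factors latent factors driving metabolite correlation; 0 gives
#'   mutually independent columns.
#' @param true_logor per-metabolite log odds ratio of disease per 1 SD of
#'   log concentration (recycled to \code{n_metabolites}).
#' @param bmi_effect_on_metabolites per-metabolite SD change in log
#'   concentration per SD of BMI (recycled).
#' @param bmi_logor log odds ratio of disease per SD of BMI.
#' @param lod_quantile fraction in [0, 1) of each metabolite's marginal
#'   distribution censored at the batch detection limit.
#' @param noise_sd SD of the independent log-scale noise term.
#' @param loadings optional fixed loading matrix
#'   (\code{n_metabolites} x \code{n_factors}); drawn once per run when NULL.
#' @param n_batches number of assay batches samples are cycled over.
#' @param seed integer seed; identical seed and config give identical output.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_pairs, n_metabolites, n_cohorts = 1L,
                       n_factors = 2L, true_logor = 0,
                       bmi_effect_on_metabolites = 0, bmi_logor = 0,
                       lod_quantile = 0, noise_sd = 1, loadings = NULL,
                       n_batches = 1L, seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              n_metabolites = as.integer(n_metabolites),
              n_cohorts = as.integer(n_cohorts),
              n_factors = as.integer(n_factors),
              true_logor = rep_len(true_logor, n_metabolites),
              bmi_effect_on_metabolites =
                rep_len(bmi_effect_on_metabolites, n_metabolites),
              bmi_logor = bmi_logor,
              lod_quantile = lod_quantile,
              noise_sd = noise_sd,
              loadings = loadings,
              n_batches = as.integer(n_batches),
              seed = as.integer(seed))
  nums <- c(cfg$true_logor, cfg$bmi_effect_on_metabolites, cfg$bmi_logor,
            cfg$lod_quantile, cfg$noise_sd, unlist(cfg$loadings))
  if (any(!is.finite(nums)))
    stop("sim_config: non-finite numeric value supplied")
  if (cfg$n_pairs < 1L) stop("n_pairs must be >= 1")
  if (cfg$n_metabolites < 1L) stop("n_metabolites must be >= 1")
  if (cfg$lod_quantile < 0 || cfg$lod_quantile >= 1)
    stop("lod_quantile must lie in [0, 1)")
  if (cfg$n_factors < 0L) stop("n_factors must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a correlated, censored metabolome
#'
#' Draws log concentrations from a factor model
#' \eqn{x = \Lambda f + \beta_{BMI} \cdot bmi + \epsilon}{x = L f + b*bmi + e}
#' (loadings drawn once per run unless fixed in the config), exponentiates
#' to concentrations, and censors each metabolite at the per-batch detection
#' limit placed at the \code{lod_quantile} of its marginal distribution.
#' Censored cells are flagged \code{below_LOD} but keep their simulated
#' values: imputation is a separate, explicit step
#' (\code{\link{impute_limits}}).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with components \code{matrix}
#'   (a \code{\link{metabolite_matrix}} with attached
#'   \code{\link{panel_spec}}) and \code{samples} (a data frame of per-sample
#'   BMI and identifiers used downstream by
#'   \code{\link{simulate_matched_pairs}}).
#' @export
simulate_metabolome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- 2L * config$n_pairs
  p <- config$n_metabolites
  k <- config$n_factors

  bmi <- stats::rnorm(n)
  if (k > 0L) {
    L <- config$loadings
    if (is.null(L)) {
      L <- matrix(stats::rnorm(p * k, sd = 1 / sqrt(max(k, 1))), p, k)
    } else {
      L <- matrix(L, p, k)
    }
    f <- matrix(stats::rnorm(n * k), n, k)
    x <- f %*% t(L)
  } else {
    x <- matrix(0, n, p)
  }
  x <- x + outer(bmi, config$bmi_effect_on_metabolites) +
    matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)

  conc <- exp(x)
  met_ids <- sprintf("met%03d", seq_len(p))
  samp_ids <- sprintf("s%05d", seq_len(n))
  dimnames(conc) <- list(samp_ids, met_ids)
  batch <- as.character(rep_len(seq_len(config$n_batches), n))

  flags <- matrix("ok", n, p, dimnames = dimnames(conc))
  classes <- rep_len(c("acylcarnitine", "amino acid", "biogenic amine",
                       "GPL", "sphingolipid"), p)
  lim <- do.call(rbind, lapply(seq_len(p), function(j) {
    out <- lapply(unique(batch), function(b) {
      v <- conc[batch == b, j]
      lod <- if (config$lod_quantile > 0)
        as.numeric(stats::quantile(v, config$lod_quantile)) else 0
      data.frame(metabolite = met_ids[j], batch = b,
                 lod = lod, lloq = lod, uloq = NA_real_)
    })
    do.call(rbind, out)
  }))
  if (config$lod_quantile > 0) {
    for (r in seq_len(nrow(lim))) {
      sel <- batch == lim$batch[r]
      j <- lim$metabolite[r]
      flags[sel, j][conc[sel, j] < lim$lod[r]] <- "below_LOD"
    }
  }
  panel <- panel_spec(
    info = data.frame(metabolite = met_ids, platform = "targeted",
                      class = classes, quantification = "semiquantified",
                      unconfirmed = FALSE),
    limits = lim)
  mat <- metabolite_matrix(conc, flags, batch, panel)
  samples <- data.frame(sample_id = samp_ids, bmi = bmi,
                        stringsAsFactors = FALSE)
  list(matrix = mat, samples = samples)
}

#' Assign matched pairs and case labels under the conditional logistic model
#'
#' Consecutive samples form a pair; both members share the matching
#' variables (age, sex, cohort, blood-draw date).  Within each pair the case
#' label goes to member 1 with probability
#' \eqn{e^{\eta_1}/(e^{\eta_1}+e^{\eta_2})}, where
#' \eqn{\eta = \sum_j \beta_j z_j + \beta_{BMI} z_{BMI}} uses z-scored log
#' concentrations.  This softmax assignment makes the 1:1 conditional
#' likelihood exactly correct, so a conditional logistic fit recovers
#' \code{true_logor} without matching-induced bias.  Non-matching risk
#' factors (smoking, pack-years, alcohol, hypertension, fasting) are drawn
#' independently per participant to exercise the adjusted models.
#'
#' @param metabolome output of \code{\link{simulate_metabolome}}.
#' @param config the same \code{\link{sim_config}}.
#' @return A data frame of participant records (one row per sample) with
#'   \code{pair_id}, \code{case}, \code{cohort} and risk-factor covariates.
#' @export
simulate_matched_pairs <- function(metabolome, config) {
  stopifnot(inherits(config, "sim_config"))
  conc <- metabolome$matrix$values
  n <- nrow(conc)
  if (n %% 2L != 0L) stop("sample count must be even to form 1:1 pairs")
  if (n < 2L * config$n_pairs) stop("metabolome has fewer than 2*n_pairs samples")
  set.seed(config$seed + 1L)

  z <- scale(log(conc))
  zbmi <- as.numeric(scale(metabolome$samples$bmi))
  eta <- as.numeric(z %*% config$true_logor) + config$bmi_logor * zbmi

  n_pairs <- n %/% 2L
  i1 <- seq(1L, n, by = 2L)
  i2 <- i1 + 1L
  p_first <- stats::plogis(eta[i1] - eta[i2])
  first_is_case <- stats::rbinom(n_pairs, 1L, p_first)
  case <- integer(n)
  case[i1] <- first_is_case
  case[i2] <- 1L - first_is_case

  pair_id <- rep(sprintf("pair%05d", seq_len(n_pairs)), each = 2L)
  cohort <- rep(sprintf("cohort%d",
                        rep_len(seq_len(config$n_cohorts), n_pairs)),
                each = 2L)
  age <- rep(round(stats::runif(n_pairs, 40, 75)), each = 2L)
  sex <- rep(sample(c("M", "F"), n_pairs, replace = TRUE), each = 2L)

  data.frame(
    sample_id = metabolome$samples$sample_id,
    pair_id = pair_id, case = case, cohort = cohort,
    age = age, sex = sex,
    bmi = metabolome$samples$bmi,
    smoking = sample(c("never", "former", "current"), n, replace = TRUE),
    pack_years = round(stats::rexp(n, rate = 1 / 10), 1),
    alcohol = round(stats::rexp(n, rate = 1 / 12), 1),
    hypertension = sample(c("ever", "never"), n, replace = TRUE),
    fasting = sample(c("<6h", ">=6h"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Configuration for the GWAS summary-statistics simulator
#'
#' @param n_snps number of instruments (>= 1).
#' @param causal_theta causal effect, SD of outcome per SD of exposure.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of the per-SNP direct
#'   (pleiotropic) effect on the outcome; mean 0, sd 0 gives valid
#'   instruments.
#' @param exposure_n,outcome_n GWAS sample sizes; standard errors follow
#'   \eqn{1/\sqrt{2f(1-f)n}} for standardized traits.
#' @param eaf_range interval within (0, 1) effect-allele frequencies are
#'   drawn from.
#' @param palindromic_frac fraction of SNPs given palindromic (A/T or C/G)
#'   allele pairs, to exercise harmonisation.
#' @param seed integer seed.
#' @return A \code{gwas_sim_config} list.
#' @export
gwas_sim_config <- function(n_snps, causal_theta = 0, pleiotropy_mean = 0,
                            pleiotropy_sd = 0, exposure_n = 7e5,
                            outcome_n = 8000, eaf_range = c(0.05, 0.95),
                            palindromic_frac = 0.1, seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), causal_theta = causal_theta,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              exposure_n = exposure_n, outcome_n = outcome_n,
              eaf_range = eaf_range,
              palindromic_frac = palindromic_frac, seed = as.integer(seed))
  if (any(!is.finite(unlist(cfg[c("causal_theta", "pleiotropy_mean",
                                  "pleiotropy_sd", "exposure_n", "outcome_n",
                                  "eaf_range", "palindromic_frac")]))))
    stop("gwas_sim_config: non-finite numeric value supplied")
  if (cfg$n_snps < 1L) stop("n_snps must be >= 1")
  if (length(eaf_range) != 2L || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] > eaf_range[2])
    stop("eaf_range must lie within (0, 1)")
  class(cfg) <- "gwas_sim_config"
  cfg
}

# Allele pairs used by the simulator; the last two are palindromic.
.allele_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("A", "T"), c("C", "G"))

#' Simulate two-sample MR summary statistics
#'
#' Per-SNP true exposure effects are drawn strong enough to pass genome-wide
#' significance (|beta/se| between roughly 6 and 20) and observed with
#' sampling noise at the SE implied by the effect-allele frequency and the
#' exposure sample size.  True outcome effects are
#' \code{causal_theta} x (true exposure effect) plus a per-SNP pleiotropic
#' intercept drawn from N(\code{pleiotropy_mean}, \code{pleiotropy_sd}^2),
#' again observed with sampling noise at the outcome-side SE.  Alleles and
#' EAFs are emitted so harmonisation can be tested; a configurable fraction
#' of SNPs is palindromic.
#'
#' @param gconfig a \code{\link{gwas_sim_config}}.
#' @param n_outcomes number of outcome (metabolite) tables to draw against
#'   the same exposure; their causal effects are recycled from
#'   \code{gconfig$causal_theta}.
#' @param thetas optional vector of per-outcome causal effects overriding
#'   \code{causal_theta}.
#' @return A list with \code{exposure} (one summary-statistics data frame
#'   with columns \code{snp, effect_allele, other_allele, eaf, beta, se,
#'   pval, n}) and \code{outcomes} (a named list of data frames in the same
#'   layout).  With \code{n_outcomes = 1} the single outcome is also exposed
#'   as \code{$outcome}.
#' @export
simulate_gwas_summary <- function(gconfig, n_outcomes = 1L, thetas = NULL) {
  stopifnot(inherits(gconfig, "gwas_sim_config"))
  set.seed(gconfig$seed)
  m <- gconfig$n_snps
  if (is.null(thetas)) thetas <- rep_len(gconfig$causal_theta, n_outcomes)
  n_outcomes <- length(thetas)

  eaf <- stats::runif(m, gconfig$eaf_range[1], gconfig$eaf_range[2])
  se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * gconfig$exposure_n)
  se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * gconfig$outcome_n)

  # True exposure effects in absolute units, anchored to a reference GWAS
  # size so that sampling noise (at the SE implied by the actual n) vanishes
  # as n grows.  Effects are oriented positive: the effect allele is taken
  # as the exposure-increasing allele, the convention that makes a mean
  # pleiotropic effect directional.  At exposure_n = n_ref the instruments
  # sit at |z| in 6-20, past genome-wide significance.
  n_ref <- 7e5
  gamma <- stats::runif(m, 6, 20) / sqrt(2 * eaf * (1 - eaf) * n_ref)
  beta_x <- gamma + stats::rnorm(m, sd = se_x)

  n_pal <- round(gconfig$palindromic_frac * m)
  pal <- seq_len(m) <= n_pal
  pair_idx <- ifelse(pal, sample(5:6, m, TRUE), sample(1:4, m, TRUE))
  ea <- vapply(pair_idx, function(i) .allele_pairs[[i]][1], "")
  oa <- vapply(pair_idx, function(i) .allele_pairs[[i]][2], "")

  snp <- sprintf("rs%06d", seq_len(m))
  exposure <- data.frame(
    snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta_x, se = se_x,
    pval = 2 * stats::pnorm(-abs(beta_x / se_x)),
    n = gconfig$exposure_n, stringsAsFactors = FALSE)

  outcomes <- lapply(seq_len(n_outcomes), function(j) {
    alpha <- stats::rnorm(m, gconfig$pleiotropy_mean, gconfig$pleiotropy_sd)
    beta_y <- thetas[j] * gamma + alpha + stats::rnorm(m, sd = se_y)
    data.frame(
      snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta_y, se = se_y,
      pval = 2 * stats::pnorm(-abs(beta_y / se_y)),
      n = gconfig$outcome_n, stringsAsFactors = FALSE)
  })
  names(outcomes) <- sprintf("met%03d", seq_len(n_outcomes))
  out <- list(exposure = exposure, outcomes = outcomes)
  if (n_outcomes == 1L) out$outcome <- outcomes[[1L]]
  out
}

#' Simulate instruments for a negative-control exposure
#'
#' Convenience wrapper around \code{\link{simulate_gwas_summary}} with the
#' causal effect forced to zero against every metabolite in the panel: the
#' exposure's instruments carry no signal into any outcome beyond the
#' configured pleiotropy and sampling noise, emulating an exposure with no
#' plausible effect on the metabolome (e.g. dental disease used to calibrate
#' the null behaviour of a profile comparison).
#'
#' @param gconfig a \code{\link{gwas_sim_config}}; its \code{causal_theta}
#'   is ignored.
#' @param n_metabolites size of the outcome panel.
#' @return As \code{\link{simulate_gwas_summary}}.
#' @export
simulate_null_exposure <- function(gconfig, n_metabolites = 1L) {
  simulate_gwas_summary(gconfig, thetas = rep(0, n_metabolites))
}
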