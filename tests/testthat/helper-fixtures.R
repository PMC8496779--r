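# Shared fixture builders: everything is generated in code at test time.

# A small matched dataset with known effects, single cohort by default.
make_dataset <- function(n_pairs = 200, n_metabolites = 3, true_logor = 0,
                         bmi_effect = 0, bmi_logor = 0, n_cohorts = 1,
                         n_factors = 0, seed = 1) {
  cfg <- sim_config(n_pairs = n_pairs, n_metabolites = n_metabolites,
                    n_cohorts = n_cohorts, n_factors = n_factors,
                    true_logor = true_logor,
                    bmi_effect_on_metabolites = bmi_effect,
                    bmi_logor = bmi_logor, seed = seed)
  met <- simulate_metabolome(cfg)
  samples <- simulate_matched_pairs(met, cfg)
  z <- log_standardize(impute_limits(met$matrix))
  list(ds = matched_dataset(samples, z), cfg = cfg, met = met)
}

# Hand-built instrument set for closed-form estimator checks.
make_instruments <- function(beta_exposure, beta_outcome, se_outcome,
                             se_exposure = rep(1e-4, length(beta_exposure)),
                             eaf = rep(0.3, length(beta_exposure))) {
  ins <- data.frame(snp = sprintf("rs%03d", seq_along(beta_exposure)),
                    beta_exposure = beta_exposure,
                    se_exposure = se_exposure,
                    beta_outcome = beta_outcome,
                    se_outcome = se_outcome, eaf = eaf,
                    stringsAsFactors = FALSE)
  class(ins) <- c("instrument_set", "data.frame")
  ins
}

# Simulated instrument set with explicit validity structure (for the
# weighted-median robustness check), bypassing allele bookkeeping.
make_sim_instruments <- function(m = 50, theta = 0.3, invalid_frac = 0,
                                 invalid_effect = 0.02, outcome_n = 5e4,
                                 seed = 1) {
  set.seed(seed)
  f <- runif(m, 0.1, 0.9)
  se_x <- 1 / sqrt(2 * f * (1 - f) * 7e5)
  se_y <- 1 / sqrt(2 * f * (1 - f) * outcome_n)
  gamma <- runif(m, 8, 20) * se_x
  n_inv <- round(invalid_frac * m)
  alpha <- c(rep(invalid_effect, n_inv), rep(0, m - n_inv))
  bx <- gamma + rnorm(m, 0, se_x)
  by <- theta * gamma + alpha + rnorm(m, 0, se_y)
  make_instruments(bx, by, se_y, se_x, f)
}

# Oracle for the 1:1 conditional MLE: coarse-to-fine grid maximisation of
# the analytic conditional log-likelihood (scalar exposure).
grid_mle <- function(dx, lo = -4, hi = 4) {
  grid <- seq(lo, hi, by = 1e-3)
  ll <- vapply(grid, conditional_loglik, numeric(1), dx = dx)
  b <- grid[which.max(ll)]
  fine <- seq(b - 2e-3, b + 2e-3, by = 1e-7)
  llf <- vapply(fine, conditional_loglik, numeric(1), dx = dx)
  fine[which.max(llf)]
}

# IVW-only MR profile of an exposure across an outcome panel (fast path for
# correlation replicates; skips the bootstrap-heavy weighted median).
ivw_profile <- function(sims, source = "mr") {
  ins_exp <- select_instruments(sims$exposure)
  rows <- lapply(names(sims$outcomes), function(m) {
    ins <- harmonize(ins_exp, sims$outcomes[[m]])
    e <- mr_ivw(ins)
    data.frame(metabolite = m, estimate = e$beta, se = e$se, p = e$p)
  })
  standardized_profile(do.call(rbind, rows), source)
}
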