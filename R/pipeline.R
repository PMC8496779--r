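#' Default pipeline configuration
#'
#' Returns the full list of configuration keys understood by
#' \code{\link{run_pipeline}}, at study-condition defaults: 1:1 matched
#' pairs spread over cohorts, a factor-structured metabolite panel with
#' detection-limit censoring, a BMI-like confounder acting on both
#' metabolites and risk, and GWAS summary panels for the exposure of
#' interest and a negative-control exposure.
#'
#' @param n_pairs,n_metabolites,n_cohorts,n_snps problem sizes.
#' @param seed master seed; stage seeds are derived from it.
#' @return Named list of configuration values.
#' @export
default_config <- function(n_pairs = 300L, n_metabolites = 40L,
                           n_cohorts = 3L, n_snps = 150L, seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_pairs = n_pairs, n_metabolites = n_metabolites,
                  n_cohorts = n_cohorts, n_factors = 3L,
                  true_logor = 0, bmi_effect_on_metabolites = 0,
                  bmi_logor = 0.3, lod_quantile = 0.02),
    qc = list(min_above = 100L),
    discovery = list(var_frac = 0.95, alpha_cohort = 0.05, min_cohorts = 2L),
    mr = list(n_snps = n_snps, causal_theta = -0.17,
              pleiotropy_mean = 0, pleiotropy_sd = 0,
              exposure_n = 7e5, outcome_n = 8000,
              p_thresh = 5e-8, r2_thresh = 0.01, n_boot = 200L)
  )
}

stage_step <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_manifest <- function(dir, stage, info) {
  info$stage <- stage
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(info, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-cohort simulation, panel QC, the matched
#' risk scan, effective-number-of-tests discovery, the exposure MR scan, the
#' instrument-specificity screen and the profile comparison (including the
#' negative-control exposure).  Each stage writes its tables tab-delimited
#' plus a JSON manifest into \code{out_dir}; a failing stage halts the run
#' with its name, preserving earlier outputs.  Reruns with identical config
#' and seeds reproduce the tables exactly.
#'
#' @param config a configuration list (\code{\link{default_config}}) or a
#'   YAML file path.
#' @param out_dir output directory (created if absent).
#' @param stages subset of stages to run, in pipeline order.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         stages = c("simulate", "qc", "risk", "discover",
                                    "mr", "pleiotropy", "compare")) {
  config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stages <- match.arg(stages, several.ok = TRUE)

  cc <- config$cohort
  scfg <- sim_config(n_pairs = cc$n_pairs, n_metabolites = cc$n_metabolites,
                     n_cohorts = cc$n_cohorts, n_factors = cc$n_factors,
                     true_logor = cc$true_logor,
                     bmi_effect_on_metabolites = cc$bmi_effect_on_metabolites,
                     bmi_logor = cc$bmi_logor,
                     lod_quantile = cc$lod_quantile,
                     seed = config$seed)

  if ("simulate" %in% stages) {
    res$simulate <- stage_step("simulate", {
      met <- simulate_metabolome(scfg)
      samples <- simulate_matched_pairs(met, scfg)
      write_matrix_tsv(met$matrix, file.path(out_dir, "concentrations.tsv"))
      utils::write.table(samples, file.path(out_dir, "samples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(out_dir, "simulate",
                     list(seed = config$seed, n_pairs = cc$n_pairs,
                          n_metabolites = cc$n_metabolites))
      list(metabolome = met, samples = samples)
    })
  }

  if ("qc" %in% stages) {
    res$qc <- stage_step("qc", {
      met <- res$simulate$metabolome
      if (is.null(met)) stop("simulate stage output not available")
      imp <- impute_limits(met$matrix)
      excl <- exclude_sparse(imp, cohort = res$simulate$samples$cohort,
                             min_above = config$qc$min_above)
      z <- log_standardize(excl$matrix, cohort = res$simulate$samples$cohort)
      write_matrix_tsv(z, file.path(out_dir, "zmatrix.tsv"))
      write_manifest(out_dir, "qc",
                     list(min_above = config$qc$min_above,
                          n_retained = ncol(z)))
      list(zmat = z, report = excl$report)
    })
  }

  if ("risk" %in% stages) {
    res$risk <- stage_step("risk", {
      ds <- matched_dataset(res$simulate$samples, res$qc$zmat)
      scan <- scan_metabolome(ds, model = "crude")
      utils::write.table(scan, file.path(out_dir, "risk_estimates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(out_dir, "risk", list(model = "crude",
                                           n_estimates = nrow(scan)))
      list(dataset = ds, scan = scan)
    })
  }

  if ("discover" %in% stages) {
    res$discover <- stage_step("discover", {
      ent <- effective_tests(res$qc$zmat, config$discovery$var_frac)
      thr <- significance_threshold(ent)
      scan <- res$risk$scan
      pooled <- scan[scan$cohort == "pooled", c("metabolite", "p")]
      per_cohort <- scan[scan$cohort != "pooled", ]
      cmat <- with(per_cohort,
                   tapply(p, list(metabolite, cohort), function(v) v[1L]))
      dr <- robust_hits(pooled, cmat, thr,
                        alpha_cohort = config$discovery$alpha_cohort,
                        min_cohorts = config$discovery$min_cohorts)
      utils::write.table(dr$table, file.path(out_dir, "discovery.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(out_dir, "discover",
                     list(ENT = ent, threshold = thr,
                          n_robust = dr$n_robust))
      list(ent = ent, threshold = thr, result = dr)
    })
  }

  mcfg <- config$mr
  n_met <- ncol(res$qc$zmat %||% matrix(nrow = 0, ncol = cc$n_metabolites))
  gcfg <- gwas_sim_config(n_snps = mcfg$n_snps,
                          causal_theta = mcfg$causal_theta,
                          pleiotropy_mean = mcfg$pleiotropy_mean,
                          pleiotropy_sd = mcfg$pleiotropy_sd,
                          exposure_n = mcfg$exposure_n,
                          outcome_n = mcfg$outcome_n,
                          seed = config$seed + 1000L)

  if ("mr" %in% stages) {
    res$mr <- stage_step("mr", {
      thetas <- rep_len(mcfg$causal_theta, n_met)
      sims <- simulate_gwas_summary(gcfg, thetas = thetas)
      names(sims$outcomes) <- colnames(res$qc$zmat)
      scan <- mr_scan(sims$exposure, sims$outcomes,
                      threshold = res$discover$threshold %||% 0.05,
                      p_thresh = mcfg$p_thresh, r2_thresh = mcfg$r2_thresh,
                      n_boot = mcfg$n_boot, seed = config$seed + 2000L)
      utils::write.table(scan, file.path(out_dir, "mr_estimates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(out_dir, "mr",
                     list(n_snps = mcfg$n_snps,
                          causal_theta = mcfg$causal_theta,
                          n_metabolites = n_met))
      list(sims = sims, scan = scan)
    })
  }

  if ("pleiotropy" %in% stages) {
    res$pleiotropy <- stage_step("pleiotropy", {
      panel <- res$mr$sims$outcomes
      cand <- names(panel)[1L]
      ins <- select_instruments(res$mr$sims$exposure,
                                p_thresh = mcfg$p_thresh,
                                r2_thresh = mcfg$r2_thresh)
      prof <- specificity_profile(ins, panel, cand)
      utils::write.table(prof$table, file.path(out_dir, "specificity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(out_dir, "pleiotropy",
                     list(candidate = cand, rank = prof$candidate_rank,
                          pleiotropic = prof$pleiotropic))
      prof
    })
  }

  if ("compare" %in% stages) {
    res$compare <- stage_step("compare", {
      scan <- res$risk$scan
      pooled <- scan[scan$cohort == "pooled", ]
      risk_prof <- standardized_profile(
        data.frame(metabolite = pooled$metabolite,
                   estimate = pooled$logor, se = pooled$se), "risk")
      ivw <- res$mr$scan[res$mr$scan$method == "IVW", ]
      mr_prof <- standardized_profile(ivw, "mr_bmi")
      corr <- profile_correlation(risk_prof, mr_prof)

      null_sims <- simulate_null_exposure(
        gwas_sim_config(n_snps = mcfg$n_snps, exposure_n = mcfg$exposure_n,
                        outcome_n = mcfg$outcome_n,
                        seed = config$seed + 3000L),
        n_metabolites = n_met)
      names(null_sims$outcomes) <- colnames(res$qc$zmat)
      null_scan <- mr_scan(null_sims$exposure, null_sims$outcomes,
                           threshold = res$discover$threshold %||% 0.05,
                           p_thresh = mcfg$p_thresh,
                           r2_thresh = mcfg$r2_thresh,
                           n_boot = mcfg$n_boot, seed = config$seed + 4000L)
      robust_ids <- res$discover$result$table$metabolite[
        res$discover$result$table$robust]
      nc <- negative_control_comparison(risk_prof, null_scan, robust_ids)
      out <- list(bmi = corr[c("rho", "p", "n_common")],
                  negative_control = nc[c("rho", "p", "n_common",
                                          "n_robust",
                                          "n_robust_mr_significant")])
      jsonlite::write_json(out, file.path(out_dir, "profile_compare.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write_manifest(out_dir, "compare", list(rho_bmi = corr$rho))
      c(out, list(null_scan = null_scan))
    })
  }

  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
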