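make_gwas <- function(snp, ea, oa, eaf, beta, se = 0.01, n = 1e5) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

test_that("instrument selection filters by p and prunes greedily by LD", {
  g <- make_gwas(c("rs1", "rs2", "rs3"), "A", "G", 0.3,
                 beta = c(0.08, 0.07, 0.001))
  sel <- select_instruments(g)
  expect_identical(sel$snp, c("rs1", "rs2"))  # rs3 fails p < 5e-8
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("rs1", "rs2"),
                                                        c("rs1", "rs2")))
  sel2 <- select_instruments(g[1:2, ], ld = ld)
  expect_identical(sel2$snp, "rs1")  # smaller p wins the correlated pair
  expect_match(attr(sel2, "provenance")$drops[["rs2"]], "LD")
  expect_error(select_instruments(g[3, , drop = FALSE]), "no instruments")
})

test_that("greedy pruning leaves no retained pair above the LD bound", {
  set.seed(5)
  m <- 20
  g <- make_gwas(sprintf("rs%02d", 1:m), "A", "G", 0.3,
                 beta = runif(m, 0.06, 0.1))
  # block LD: 4 blocks of 5, high R2 within, none across
  ld <- matrix(0, m, m, dimnames = list(g$snp, g$snp))
  for (b in 0:3) ld[b * 5 + 1:5, b * 5 + 1:5] <- 0.8
  diag(ld) <- 1
  sel <- select_instruments(g, ld = ld, r2_thresh = 0.01)
  expect_equal(nrow(sel), 4L)
  pairs <- combn(sel$snp, 2)
  expect_true(all(ld[t(pairs)] < 0.01))
})

test_that("harmonisation aligns alleles, flips betas and drops ambiguity", {
  ex <- make_gwas(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c("G", "T", "G"),
                  c(0.3, 0.5, 0.3), beta = 0.1)
  ou <- make_gwas(c("rs1", "rs2", "rs3"), c("G", "A", "A"), c("A", "T", "G"),
                  c(0.7, 0.5, 0.3), beta = c(0.10, 0.2, 0.05))
  h <- harmonize(ex, ou)
  # rs1: outcome effect allele is the exposure's other allele -> flip
  expect_equal(h$beta_outcome[h$snp == "rs1"], -0.10)
  # rs2: palindromic A/T at EAF 0.5 -> dropped
  expect_false("rs2" %in% h$snp)
  expect_match(attr(h, "drops")[["rs2"]], "palindromic")
  # rs3: already aligned -> untouched
  expect_equal(h$beta_outcome[h$snp == "rs3"], 0.05)
  # fully aligned tables come back identical
  h2 <- harmonize(ex[3, , drop = FALSE], ou[3, , drop = FALSE])
  expect_equal(h2$beta_outcome, ou$beta[3])
  expect_equal(h2$eaf, ex$eaf[3])
})

test_that("allele mismatches and strand flips are handled", {
  ex <- make_gwas(c("rs1", "rs2"), c("A", "A"), c("G", "G"), 0.3, 0.1)
  ou <- make_gwas(c("rs1", "rs2"), c("T", "A"), c("C", "C"), 0.3,
                  c(0.07, 0.07))
  h <- harmonize(ex, ou)
  # rs1: strand-flipped same orientation, kept as-is
  expect_equal(h$beta_outcome[h$snp == "rs1"], 0.07)
  # rs2: A/C vs A/G is unresolvable
  expect_false("rs2" %in% h$snp)
  expect_match(attr(h, "drops")[["rs2"]], "mismatch")
  expect_error(harmonize(ex[2, , drop = FALSE], ou[2, , drop = FALSE]),
               "no SNPs")
})

test_that("IVW reproduces the closed-form weighted least squares", {
  # single SNP: Wald ratio
  one <- make_instruments(0.1, 0.05, 0.01)
  e1 <- mr_ivw(one)
  expect_equal(e1$beta, 0.5)
  expect_match(e1$note, "Wald")
  # three-SNP fixture against the analytic WLS-through-origin solution
  ins <- make_instruments(c(0.1, 0.2, 0.1), c(0.02, 0.04, 0.03),
                          c(0.01, 0.01, 0.02))
  w <- 1 / ins$se_outcome^2
  beta_wls <- sum(w * ins$beta_exposure * ins$beta_outcome) /
    sum(w * ins$beta_exposure^2)
  e <- mr_ivw(ins)
  expect_equal(e$beta, beta_wls, tolerance = 1e-10)
  expect_equal(e$beta, 0.2048, tolerance = 1e-3)
  # and against unweighted-equivalent lm through the origin
  fit <- lm(beta_outcome ~ beta_exposure - 1, data = ins, weights = w)
  expect_equal(e$beta, unname(coef(fit)), tolerance = 1e-10)
})

test_that("IVW with the intercept constrained to zero equals the origin fit", {
  set.seed(6)
  for (i in 1:5) {
    ins <- make_sim_instruments(20, theta = runif(1, -0.5, 0.5), seed = 40 + i)
    w <- 1 / ins$se_outcome^2
    fit <- lm(beta_outcome ~ beta_exposure - 1, data = ins, weights = w)
    expect_equal(mr_ivw(ins)$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers exact lines and exact affine relations", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  ins <- make_instruments(bx, 0.5 * bx, rep(0.01, 4))
  e <- mr_egger(ins)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0, tolerance = 1e-10)
  ins2 <- make_instruments(bx, 0.03 + 0.5 * bx, rep(0.01, 4))
  e2 <- mr_egger(ins2)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$egger_intercept, 0.03, tolerance = 1e-10)
  expect_error(mr_egger(ins[1:2, ]), "at least 3")
})

test_that("Egger orients exposure betas positive before fitting", {
  bx <- c(-0.05, 0.1, -0.15, 0.2)
  # outcome lies on by = 0.02 + 0.4*bx in the oriented (bx > 0) frame
  by <- ifelse(bx < 0, -(0.02 + 0.4 * abs(bx)), 0.02 + 0.4 * bx)
  ins <- make_instruments(bx, by, rep(0.01, 4))
  e <- mr_egger(ins)
  expect_equal(e$beta, 0.4, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.02, tolerance = 1e-10)
})

test_that("weighted median interpolates the 50 percent weight point", {
  # equal weights, ratios 0.2/0.5/0.9: the middle ratio
  ins <- make_instruments(c(1, 1, 1), c(0.2, 0.5, 0.9), c(1, 1, 1))
  expect_equal(mr_weighted_median(ins, 10, 1)$beta, 0.5)
  # one SNP carrying most of the weight dominates
  ins2 <- make_instruments(c(1, 1, 1), c(0.2, 0.5, 0.9),
                           c(1, 1, 0.05))
  expect_equal(mr_weighted_median(ins2, 10, 1)$beta, 0.9, tolerance = 0.05)
  # zero exposure beta is dropped with a warning
  ins3 <- make_instruments(c(0, 1, 1, 1), c(0.1, 0.2, 0.5, 0.9), rep(1, 4))
  expect_warning(e3 <- mr_weighted_median(ins3, 10, 1), "zero exposure")
  expect_equal(e3$n_snps, 3L)
})

test_that("weighted median stays within the ratio range and is reproducible", {
  set.seed(7)
  for (i in 1:10) {
    ins <- make_sim_instruments(15, theta = runif(1, -1, 1), seed = 70 + i)
    est <- mr_weighted_median(ins, 50, seed = i)
    theta <- ins$beta_outcome / ins$beta_exposure
    expect_gte(est$beta, min(theta))
    expect_lte(est$beta, max(theta))
    expect_identical(est, mr_weighted_median(ins, 50, seed = i))
  }
})

test_that("estimators are equivariant under outcome negation", {
  ins <- make_sim_instruments(25, theta = 0.4, seed = 80)
  neg <- ins
  neg$beta_outcome <- -neg$beta_outcome
  expect_equal(mr_ivw(neg)$beta, -mr_ivw(ins)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(neg)$beta, -mr_egger(ins)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(neg, 100, 3)$beta,
               -mr_weighted_median(ins, 100, 3)$beta, tolerance = 1e-9)
})

test_that("weighted median resists 40 percent invalid instruments", {
  res <- t(sapply(1:25, function(i) {
    ins <- make_sim_instruments(50, theta = 0.3, invalid_frac = 0.4,
                                invalid_effect = 0.02, outcome_n = 1e7,
                                seed = 90 + i)
    c(wm = mr_weighted_median(ins, 100, i)$beta, ivw = mr_ivw(ins)$beta)
  }))
  expect_lt(abs(mean(res[, "wm"]) - 0.3), 0.03)
  expect_gt(mean(res[, "ivw"]) - 0.3, 0.05)  # IVW measurably biased upward
})

test_that("panel scan flags the causal metabolite and is deterministic", {
  g <- gwas_sim_config(120, seed = 101, outcome_n = 5e4)
  sims <- simulate_gwas_summary(g, thetas = c(-0.17, 0, 0))
  scan <- mr_scan(sims$exposure, sims$outcomes, threshold = 1e-3,
                  n_boot = 50, seed = 1)
  ivw <- scan[scan$method == "IVW", ]
  expect_true(ivw$significant[ivw$metabolite == "met001"])
  expect_false(any(ivw$significant[ivw$metabolite != "met001"]))
  # identical outcome tables give identical estimates
  dup <- list(a = sims$outcomes[[1]], b = sims$outcomes[[1]])
  scan2 <- mr_scan(sims$exposure, dup, threshold = 1e-3, n_boot = 50, seed = 1)
  a <- scan2[scan2$metabolite == "a", -1]
  b <- scan2[scan2$metabolite == "b", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})
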