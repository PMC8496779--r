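make_qc_matrix <- function() {
  vals <- matrix(c(0.05, 3.7, 150,
                   0.5,  2.0, 80,
                   NA,   1.0, 90), 3, 3, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), c("m1", "m2", "m3")))
  flags <- matrix("ok", 3, 3, dimnames = dimnames(vals))
  flags[1, "m1"] <- "below_LLOQ"
  flags[1, "m3"] <- "above_ULOQ"
  flags[3, "m1"] <- "missing_internal_standard"
  panel <- panel_spec(
    info = data.frame(metabolite = c("m1", "m2", "m3"), platform = "targeted",
                      class = c("amino acid", "amino acid", "GPL"),
                      quantification = c("quantified", "quantified",
                                         "semiquantified"),
                      unconfirmed = FALSE),
    limits = data.frame(metabolite = c("m1", "m2", "m3"), batch = "1",
                        lod = c(0.1, 0.1, 1), lloq = c(0.2, 0.2, 2),
                        uloq = c(1000, 1000, 100)))
  metabolite_matrix(vals, flags, panel = panel)
}

test_that("limit-based imputation applies the half-limit and ULOQ-cap rules", {
  mm <- make_qc_matrix()
  out <- impute_limits(mm)
  expect_equal(out$values[1, "m1"], 0.1)     # half the LLOQ of 0.2
  expect_equal(out$values[1, "m3"], 100)     # capped at the ULOQ
  expect_equal(out$values[1, "m2"], 3.7)     # in-range value untouched
  expect_true(is.na(out$values[3, "m1"]))    # internal standard out of range
  # idempotent
  expect_identical(impute_limits(out), out)
})

test_that("imputation with an absent limit names the metabolite", {
  mm <- make_qc_matrix()
  mm$panel$limits$uloq[3] <- NA
  expect_error(impute_limits(mm), "m3")
})

test_that("semiquantified compounds are imputed at half the batch LOD", {
  vals <- matrix(c(0.01, 5), 2, 1, dimnames = list(c("s1", "s2"), "sq"))
  flags <- matrix(c("below_LOD", "ok"), 2, 1, dimnames = dimnames(vals))
  panel <- panel_spec(
    info = data.frame(metabolite = "sq", platform = "targeted", class = "GPL",
                      quantification = "semiquantified", unconfirmed = FALSE),
    limits = data.frame(metabolite = "sq", batch = "1", lod = 0.5, lloq = 0.5,
                        uloq = NA))
  out <- impute_limits(metabolite_matrix(vals, flags, panel = panel))
  expect_equal(out$values[1, 1], 0.25)
})

test_that("sparsity exclusion is strict below the cutoff and matches a recount", {
  set.seed(1)
  n <- 240
  cohort <- rep(c("A", "B"), each = n / 2)
  vals <- matrix(rlnorm(n * 4), n, 4,
                 dimnames = list(paste0("s", 1:n), paste0("m", 1:4)))
  flags <- matrix("ok", n, 4, dimnames = dimnames(vals))
  flags[1:21, 1] <- "below_LOD"   # 99 above in cohort A -> excluded
  flags[1:20, 2] <- "below_LOD"   # exactly 100 above in A -> retained
  flags[cbind(sample(which(cohort == "B"), 30), 3)] <- "below_LLOQ"  # 90 in B
  out <- exclude_sparse(metabolite_matrix(vals, flags), cohort, min_above = 100)
  expect_identical(colnames(out$matrix$values), c("m2", "m4"))
  # brute-force recount oracle
  for (m in paste0("m", 1:4)) {
    for (co in c("A", "B")) {
      manual <- sum(flags[cohort == co, m] %in% c("ok", "above_ULOQ"))
      expect_equal(out$report$counts[m, co], manual)
    }
  }
  expect_identical(unname(out$report$retained),
                   unname(apply(out$report$counts >= 100, 1, all)))
})

test_that("median rescaling sets observed medians to 1 and fills minima", {
  vals <- matrix(c(2, 4, 8), 3, 1, dimnames = list(paste0("s", 1:3), "m"))
  expect_equal(unname(rescale_untargeted(vals)[, 1]), c(0.5, 1, 2))
  v2 <- matrix(c(1, NA, 3), 3, 1, dimnames = list(paste0("s", 1:3), "m"))
  out <- rescale_untargeted(v2)
  expect_equal(unname(out[2, 1]), 1 / 2)  # minimum observed after scaling
  # post-condition on a random fixture: median of originally observed = 1
  set.seed(2)
  v3 <- matrix(rlnorm(200), 40, 5, dimnames = list(NULL, paste0("m", 1:5)))
  v3[sample(200, 20)] <- NA
  out3 <- rescale_untargeted(v3)
  for (j in 1:5)
    expect_equal(median(out3[!is.na(v3[, j]), j]), 1)
  expect_error(rescale_untargeted(matrix(NA_real_, 3, 1,
                                         dimnames = list(NULL, "bad"))), "bad")
})

test_that("derived ratios follow the molar arithmetic", {
  vals <- matrix(c(100, 50, 150, 50, 50,
                   10, 10, 10, 0, 0), 2, 5, byrow = TRUE,
                 dimnames = list(c("s1", "s2"),
                                 c("Leu", "Ile", "Val", "Phe", "Tyr")))
  out <- derive_ratios(vals)
  expect_equal(unname(out[1, "fischer_ratio"]), 3.0)
  expect_true(is.na(out[2, "fischer_ratio"]))  # zero denominator -> missing
  expect_equal(ncol(out), ncol(vals) + 1L)
  defs <- list(bcaa = list(numerator = c("Leu", "Ile", "Val"),
                           denominator = NULL),
               r2 = list(numerator = "Leu", denominator = "Phe"))
  expect_equal(ncol(derive_ratios(vals, defs)), ncol(vals) + 2L)
  expect_error(derive_ratios(vals, list(x = list(numerator = "nope",
                                                 denominator = "Phe"))),
               "nope")
})

test_that("log z-scoring yields unit-scale columns regardless of log base", {
  set.seed(3)
  vals <- matrix(rlnorm(300, sdlog = 0.4), 60, 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
  z <- log_standardize(vals)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # base change is absorbed by the z-score
  z10 <- scale(log10(vals))
  expect_equal(unname(z), unname(z10[, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # scaling a raw column by a positive constant changes nothing
  vals2 <- vals; vals2[, 2] <- vals2[, 2] * 37
  expect_equal(log_standardize(vals2), z, tolerance = 1e-10)
  expect_error(log_standardize(vals - 10), "non-positive")
  expect_warning(z3 <- log_standardize(cbind(vals, const = 5)), "const")
  expect_equal(ncol(z3), 5L)
})

test_that("per-cohort z-scoring standardises within each cohort", {
  set.seed(4)
  vals <- matrix(rlnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  cohort <- rep(c("x", "y"), each = 50)
  vals[cohort == "y", ] <- vals[cohort == "y", ] * 10
  z <- log_standardize(vals, cohort = cohort)
  for (co in c("x", "y")) {
    expect_equal(unname(colMeans(z[cohort == co, ])), c(0, 0),
                 tolerance = 1e-12)
    expect_equal(unname(apply(z[cohort == co, ], 2, sd)), c(1, 1),
                 tolerance = 1e-12)
  }
})

test_that("replicate CVs reproduce the direct formula", {
  reps <- data.frame(metabolite = "m", batch = rep(c("b1", "b2", "b3"), each = 3),
                     value = c(5, 5, 5, 90, 100, 110, 45, 50, 55))
  out <- compute_cv(reps)
  expect_equal(out$cv_intra, 10)  # median of (0, 10, 10)
  bm <- c(5, 100, 50)
  expect_equal(out$cv_inter, 100 * sd(bm) / mean(bm))
  # fewer than two replicates -> missing CV
  one <- data.frame(metabolite = "m", batch = "b", value = 3)
  expect_true(is.na(compute_cv(one)$cv_inter))
})

test_that("panel merging reproduces inclusion-exclusion counts", {
  # two untargeted deliveries: 1,308 and 1,302 features with 1,275 shared
  a <- paste0("feat", 1:1308)
  b <- paste0("feat", c(1:1275, 2000:2026))
  m <- merge_panels(a, b)
  expect_equal(m$n_union, 1335)
  expect_equal(m$n_intersection, 1275)
  expect_equal(m$n_union, m$n_a + m$n_b - m$n_intersection)
  # after sparsity exclusion: 1,222 and 1,126 with 1,118 shared
  a2 <- paste0("f", 1:1222)
  b2 <- paste0("f", c(1:1118, 3000:3007))
  expect_equal(merge_panels(a2, b2)$n_union, 1230)
  # disjoint panels and canonicalisation
  expect_equal(merge_panels(letters[1:3], LETTERS[4:7])$n_union, 7)
  m2 <- merge_panels(c("Glutamate ", "ala"), c("glutamate", "gly"))
  expect_equal(m2$n_intersection, 1)
  expect_equal(m2$alias$panel_a, "Glutamate ")
})
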