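#' Impute values outside the quantification limits
#'
#' Applies the standard limit-based rules for targeted panels: values below
#' the lower limit of quantification (or below the batch LOD for
#' semiquantified compound classes) are replaced by half the relevant limit;
#' values above the upper limit of quantification are capped at the ULOQ.
#' Cells flagged \code{missing_internal_standard} are left missing.  The
#' operation is idempotent: re-applying it changes nothing.
#'
#' @param mat a \code{\link{metabolite_matrix}} with an attached panel.
#' @param panel optional \code{\link{panel_spec}} overriding the attached one.
#' @return The matrix with flagged cells imputed.
#' @export
impute_limits <- function(mat, panel = NULL) {
  stopifnot(inherits(mat, "metabolite_matrix"))
  if (is.null(panel)) panel <- mat$panel
  if (is.null(panel)) stop("no panel_spec supplied or attached")
  lim <- panel$limits
  key <- paste(lim$metabolite, lim$batch, sep = "\r")
  lod <- stats::setNames(lim$lod, key)
  lloq <- stats::setNames(lim$lloq, key)
  uloq <- stats::setNames(lim$uloq, key)

  vals <- mat$values
  flags <- mat$flags
  errors <- character(0)
  for (j in colnames(vals)) {
    fj <- flags[, j]
    if (all(fj == "ok")) next
    kj <- paste(j, mat$batch, sep = "\r")
    lo_lod <- fj == "below_LOD"
    lo_lloq <- fj == "below_LLOQ"
    hi <- fj == "above_ULOQ"
    if (any(lo_lod)) {
      rep_val <- lod[kj][lo_lod] / 2
      if (any(is.na(rep_val))) errors <- c(errors, paste0(j, ": LOD absent"))
      vals[lo_lod, j] <- rep_val
    }
    if (any(lo_lloq)) {
      rep_val <- lloq[kj][lo_lloq] / 2
      if (any(is.na(rep_val))) errors <- c(errors, paste0(j, ": LLOQ absent"))
      vals[lo_lloq, j] <- rep_val
    }
    if (any(hi)) {
      rep_val <- uloq[kj][hi]
      if (any(is.na(rep_val))) errors <- c(errors, paste0(j, ": ULOQ absent"))
      vals[hi, j] <- rep_val
    }
    vals[fj == "missing_internal_standard", j] <- NA_real_
  }
  if (length(errors))
    stop("limit absent for flagged cells:\n  ",
         paste(unique(errors), collapse = "\n  "))
  mat$values <- vals
  mat
}

#' Exclude metabolites sparse above the detection limit in any cohort
#'
#' A metabolite is dropped when it has fewer than \code{min_above} values
#' above the LOD/LLOQ in at least one cohort ("less than" is strict: a count
#' of exactly \code{min_above} retains).  Counts are recorded per metabolite
#' and cohort in a QC report.
#'
#' @param mat a \code{\link{metabolite_matrix}}.
#' @param cohort per-sample cohort labels covering every row.
#' @param min_above minimum above-limit count required in every cohort.
#' @return A list with \code{matrix} (the retained columns) and \code{report}
#'   (class \code{qc_report}: per-metabolite above-limit counts per cohort
#'   and the retained flag).
#' @export
exclude_sparse <- function(mat, cohort, min_above = 100L) {
  stopifnot(inherits(mat, "metabolite_matrix"),
            length(cohort) == nrow(mat$values))
  above <- mat$flags %in% c("ok", "above_ULOQ")
  dim(above) <- dim(mat$flags)
  cohorts <- sort(unique(as.character(cohort)))
  counts <- sapply(cohorts, function(cc)
    colSums(above[cohort == cc, , drop = FALSE]))
  counts <- matrix(counts, ncol = length(cohorts),
                   dimnames = list(colnames(mat$values), cohorts))
  retained <- apply(counts >= min_above, 1L, all)
  keep <- names(retained)[retained]
  mat$values <- mat$values[, keep, drop = FALSE]
  mat$flags <- mat$flags[, keep, drop = FALSE]
  if (!is.null(mat$panel)) {
    mat$panel$info <- mat$panel$info[mat$panel$info$metabolite %in% keep, ]
    mat$panel$limits <- mat$panel$limits[mat$panel$limits$metabolite %in% keep, ]
  }
  report <- structure(list(counts = counts, retained = retained,
                           min_above = min_above),
                      class = "qc_report")
  list(matrix = mat, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", sum(x$retained), "of", length(x$retained),
      "metabolites retained (min", x$min_above, "above limit per cohort)\n")
  invisible(x)
}

#' Median-rescale an untargeted panel and impute minima
#'
#' Each metabolite is divided by the median of its observed values (so the
#' observed median becomes 1), then missing values are filled with the
#' minimum observed (post-scaling) value — the standard normalisation for
#' untargeted LC-MS feature tables reported in raw area counts.
#'
#' @param mat a \code{\link{metabolite_matrix}} (or plain numeric matrix).
#' @return The rescaled object, same class as the input.
#' @export
rescale_untargeted <- function(mat) {
  vals <- if (inherits(mat, "metabolite_matrix")) mat$values else mat
  stopifnot(is.matrix(vals))
  all_na <- colSums(!is.na(vals)) == 0L
  if (any(all_na))
    stop("all-missing metabolite(s): ",
         paste(colnames(vals)[all_na], collapse = ", "))
  med <- apply(vals, 2L, stats::median, na.rm = TRUE)
  vals <- sweep(vals, 2L, med, "/")
  for (j in seq_len(ncol(vals))) {
    nas <- is.na(vals[, j])
    if (any(nas)) vals[nas, j] <- min(vals[!nas, j])
  }
  if (inherits(mat, "metabolite_matrix")) { mat$values <- vals; mat } else vals
}

#' Predefined sums and ratios, including the Fischer ratio
#'
#' @return Named list of ratio definitions (each a list with \code{numerator}
#'   and \code{denominator} metabolite-id vectors; a sum has denominator
#'   \code{NULL}); the default carries the Fischer ratio
#'   (Leu + Ile + Val) / (Phe + Tyr), a clinical liver-function indicator
#'   whose lower values signal hepatic dysfunction (orientation is metadata
#'   only, it does not alter the arithmetic).
#' @export
default_ratios <- function() {
  list(
    fischer_ratio = list(numerator = c("Leu", "Ile", "Val"),
                         denominator = c("Phe", "Tyr"),
                         note = "lower values indicate liver dysfunction")
  )
}

#' Append derived sums and ratios as pseudo-metabolites
#'
#' Each definition contributes one new column: the molar sum of its
#' numerator constituents divided by the sum of its denominator constituents
#' (or the plain sum when no denominator is given).  A sample missing any
#' constituent, or with a zero denominator, gets a missing ratio rather than
#' an infinity.
#'
#' @param mat a \code{\link{metabolite_matrix}} or numeric matrix of
#'   concentrations (pre log-transform).
#' @param ratios named list of definitions, as \code{\link{default_ratios}}.
#' @return The input with one appended column per definition.
#' @export
derive_ratios <- function(mat, ratios = default_ratios()) {
  vals <- if (inherits(mat, "metabolite_matrix")) mat$values else mat
  stopifnot(is.matrix(vals))
  out <- matrix(NA_real_, nrow(vals), length(ratios),
                dimnames = list(rownames(vals), names(ratios)))
  for (i in seq_along(ratios)) {
    def <- ratios[[i]]
    miss <- setdiff(c(def$numerator, def$denominator), colnames(vals))
    if (length(miss))
      stop("ratio '", names(ratios)[i], "': constituent(s) absent: ",
           paste(miss, collapse = ", "))
    num <- rowSums(vals[, def$numerator, drop = FALSE])
    if (is.null(def$denominator)) {
      out[, i] <- num
    } else {
      den <- rowSums(vals[, def$denominator, drop = FALSE])
      r <- num / den
      r[!is.finite(r)] <- NA_real_
      out[, i] <- r
    }
  }
  if (inherits(mat, "metabolite_matrix")) {
    mat$values <- cbind(mat$values, out)
    newf <- matrix("ok", nrow(out), ncol(out), dimnames = dimnames(out))
    newf[is.na(out)] <- "missing_internal_standard"
    mat$flags <- cbind(mat$flags, newf)
    if (!is.null(mat$panel)) {
      mat$panel$info <- rbind(
        mat$panel$info,
        data.frame(metabolite = colnames(out), platform = "targeted",
                   class = "ratio", quantification = "quantified",
                   unconfirmed = FALSE))
    }
    mat
  } else cbind(vals, out)
}

#' Log-transform and z-score a concentration matrix
#'
#' Natural log followed by per-metabolite centring and scaling to unit SD
#' over non-missing values.  Because z-scoring absorbs any multiplicative
#' constant, the log base is immaterial.  Scaling is performed within cohort
#' when labels are given (each cohort is QC'd and standardised before
#' pooling); pass \code{cohort = NULL} for a single global scaling.
#' Zero-variance columns cannot be z-scored and are dropped with a warning.
#'
#' @param mat a \code{\link{metabolite_matrix}} or numeric matrix of
#'   strictly positive concentrations (run \code{\link{impute_limits}}
#'   first).
#' @param cohort optional per-sample cohort labels for within-cohort
#'   scaling.
#' @return A plain numeric z-matrix (samples x metabolites).
#' @export
log_standardize <- function(mat, cohort = NULL) {
  vals <- if (inherits(mat, "metabolite_matrix")) mat$values else mat
  stopifnot(is.matrix(vals))
  if (any(vals <= 0, na.rm = TRUE))
    stop("non-positive concentration found; impute limits before log transform")
  lx <- log(vals)
  zscore <- function(m) {
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2L, stats::sd, na.rm = TRUE)
    sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  }
  if (is.null(cohort)) {
    z <- zscore(lx)
  } else {
    stopifnot(length(cohort) == nrow(lx))
    z <- lx
    for (cc in unique(cohort)) {
      sel <- cohort == cc
      z[sel, ] <- zscore(lx[sel, , drop = FALSE])
    }
  }
  const <- apply(z, 2L, function(v) any(is.nan(v) | is.infinite(v)))
  if (any(const)) {
    warning("dropping zero-variance metabolite(s): ",
            paste(colnames(z)[const], collapse = ", "))
    z <- z[, !const, drop = FALSE]
  }
  if (ncol(z) == 0L) stop("zero variance in every column")
  z
}

#' Intra- and inter-batch coefficients of variation from QC replicates
#'
#' CV is the sample SD over the mean, in percent.  The intra-batch CV of a
#' metabolite is the median of its per-batch CVs; the inter-batch CV is the
#' CV of the batch means.  Groups with fewer than two replicates yield a
#' missing CV.
#'
#' @param replicates data frame with columns \code{metabolite}, \code{batch}
#'   and \code{value} (QC-sample measurements).
#' @return Data frame with one row per metabolite: \code{cv_intra} and
#'   \code{cv_inter}, both in percent.
#' @export
compute_cv <- function(replicates) {
  stopifnot(all(c("metabolite", "batch", "value") %in% names(replicates)))
  cv <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  }
  mets <- unique(replicates$metabolite)
  res <- lapply(mets, function(m) {
    d <- replicates[replicates$metabolite == m, ]
    per_batch <- tapply(d$value, d$batch, cv)
    batch_means <- tapply(d$value, d$batch, mean, na.rm = TRUE)
    data.frame(metabolite = m,
               cv_intra = stats::median(per_batch, na.rm = TRUE),
               cv_inter = cv(as.numeric(batch_means)))
  })
  do.call(rbind, res)
}

#' Merge two platform panels by canonical metabolite id
#'
#' Identifiers are canonicalised (whitespace-trimmed, case-folded) before
#' set operations; the original spellings are preserved in the output.
#' Metabolites measured on both platforms are kept as distinct columns
#' downstream — they are never averaged — but linked here through an alias
#' map.
#'
#' @param ids_a,ids_b metabolite identifier vectors of the two panels.
#' @return A list with \code{union}, \code{intersection}, \code{only_a},
#'   \code{only_b} (canonical ids), the counts \code{n_union} =
#'   |A| + |B| - |A n B|, and \code{alias} (data frame mapping canonical id
#'   to the original spelling on each panel where shared).
#' @export
merge_panels <- function(ids_a, ids_b) {
  canon <- function(x) tolower(trimws(x))
  ca <- canon(ids_a); cb <- canon(ids_b)
  if (anyDuplicated(ca) || anyDuplicated(cb))
    warning("duplicate ids within a panel after canonicalisation")
  ua <- unique(ca); ub <- unique(cb)
  inter <- intersect(ua, ub)
  uni <- union(ua, ub)
  alias <- data.frame(
    canonical = inter,
    panel_a = ids_a[match(inter, ca)],
    panel_b = ids_b[match(inter, cb)],
    stringsAsFactors = FALSE)
  list(union = uni, intersection = inter,
       only_a = setdiff(ua, ub), only_b = setdiff(ub, ua),
       n_a = length(ua), n_b = length(ub),
       n_intersection = length(inter), n_union = length(uni),
       alias = alias)
}
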