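#' Panel specification for a metabolomics assay
#'
#' Describes each metabolite column of a concentration matrix: the measuring
#' platform, chemical class, whether the compound is fully quantified or
#' semiquantified, whether its identity is unconfirmed, and the batch-specific
#' quantification limits (LOD, LLOQ, ULOQ) used for limit-based imputation.
#'
#' @param info data frame with one row per metabolite and columns
#'   \code{metabolite}, \code{platform} ("targeted" or "untargeted"),
#'   \code{class}, \code{quantification} ("quantified" or "semiquantified")
#'   and \code{unconfirmed} (logical).
#' @param limits data frame of per-batch limits with columns
#'   \code{metabolite}, \code{batch}, \code{lod}, \code{lloq}, \code{uloq}.
#'   Missing limits are allowed (\code{NA}); where present they must satisfy
#'   LOD <= LLOQ <= ULOQ.
#' @return An object of class \code{panel_spec}.
#' @export
panel_spec <- function(info, limits) {
  stopifnot(is.data.frame(info), is.data.frame(limits))
  need <- c("metabolite", "platform", "class", "quantification", "unconfirmed")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop("panel info lacks columns: ", paste(miss, collapse = ", "))
  need_l <- c("metabolite", "batch", "lod", "lloq", "uloq")
  miss <- setdiff(need_l, names(limits))
  if (length(miss))
    stop("panel limits lack columns: ", paste(miss, collapse = ", "))
  bad <- with(limits,
    (!is.na(lod) & !is.na(lloq) & lod > lloq) |
    (!is.na(lloq) & !is.na(uloq) & lloq > uloq))
  if (any(bad))
    stop("limit ordering violated (need LOD <= LLOQ <= ULOQ) for: ",
         paste(unique(limits$metabolite[bad]), collapse = ", "))
  structure(list(info = info, limits = limits), class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("panel_spec:", nrow(x$info), "metabolites,",
      length(unique(x$limits$batch)), "batch(es)\n")
  print(table(platform = x$info$platform, quantification = x$info$quantification))
  invisible(x)
}

# Cell-level flags a metabolite matrix may carry.
FLAG_LEVELS <- c("ok", "below_LOD", "below_LLOQ", "above_ULOQ",
                 "missing_internal_standard")

#' Samples-by-metabolites concentration matrix
#'
#' The container every QC and scan stage transforms: a numeric matrix of
#' nonnegative concentrations (samples as rows), a parallel matrix of
#' cell-level flags (\code{ok}, \code{below_LOD}, \code{below_LLOQ},
#' \code{above_ULOQ}, \code{missing_internal_standard}), per-sample batch
#' labels and an attached \code{\link{panel_spec}}.
#'
#' @param values numeric matrix, samples x metabolites, with dimnames.
#' @param flags character matrix of the same shape; defaults to all
#'   \code{"ok"} (with \code{NA} cells flagged
#'   \code{"missing_internal_standard"}).
#' @param batch per-sample batch labels; defaults to a single batch.
#' @param panel optional \code{\link{panel_spec}} covering every column.
#' @return An object of class \code{metabolite_matrix}.
#' @export
metabolite_matrix <- function(values, flags = NULL, batch = NULL, panel = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("met", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(flags)) {
    flags <- matrix("ok", nrow(values), ncol(values), dimnames = dimnames(values))
    flags[is.na(values)] <- "missing_internal_standard"
  }
  stopifnot(identical(dim(flags), dim(values)))
  if (!all(flags %in% FLAG_LEVELS))
    stop("unknown flag value(s): ",
         paste(setdiff(unique(c(flags)), FLAG_LEVELS), collapse = ", "))
  if (is.null(batch)) batch <- rep("1", nrow(values))
  stopifnot(length(batch) == nrow(values))
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "panel_spec"))
    missing_cols <- setdiff(colnames(values), panel$info$metabolite)
    if (length(missing_cols))
      stop("matrix columns absent from panel: ",
           paste(missing_cols, collapse = ", "))
  }
  structure(list(values = values, flags = flags,
                 batch = as.character(batch), panel = panel),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat("metabolite_matrix:", nrow(x$values), "samples x",
      ncol(x$values), "metabolites\n")
  tt <- table(factor(c(x$flags), levels = FLAG_LEVELS))
  cat("flags:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$values)

#' Matched case-control dataset
#'
#' Binds participant records (case status, matched-set id, cohort and
#' risk-factor covariates) to a z-scored exposure matrix for conditional
#' logistic analysis.  Every matched set must contain exactly one case and
#' one control.
#'
#' @param samples data frame with at least \code{sample_id}, \code{pair_id},
#'   \code{case} (0/1) and \code{cohort}; risk-factor columns (\code{bmi},
#'   \code{smoking}, \code{pack_years}, \code{alcohol}, \code{hypertension},
#'   \code{fasting}) are used by the adjusted models when present.
#' @param zmat numeric matrix of exposures (typically the output of
#'   \code{\link{log_standardize}}) with rownames matching
#'   \code{samples$sample_id}.
#' @return An object of class \code{matched_dataset}.
#' @export
matched_dataset <- function(samples, zmat) {
  stopifnot(is.data.frame(samples), is.matrix(zmat))
  need <- c("sample_id", "pair_id", "case", "cohort")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples lack columns: ", paste(miss, collapse = ", "))
  if (!all(samples$case %in% c(0, 1)))
    stop("case must be coded 0/1")
  cc <- tapply(samples$case, samples$pair_id, sum)
  sz <- tapply(samples$case, samples$pair_id, length)
  if (any(sz != 2L) || any(cc != 1L))
    stop("every pair must hold exactly one case and one control")
  if (is.null(rownames(zmat)) ||
      !all(samples$sample_id %in% rownames(zmat)))
    stop("zmat rownames must cover all sample ids")
  zmat <- zmat[as.character(samples$sample_id), , drop = FALSE]
  structure(list(samples = samples, zmat = zmat), class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  cat("matched_dataset:", nrow(x$samples) / 2, "pairs,",
      ncol(x$zmat), "exposures,",
      length(unique(x$samples$cohort)), "cohort(s)\n")
  invisible(x)
}
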