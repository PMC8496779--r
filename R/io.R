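# Tab-delimited and JSON interchange for every stage.

#' Write / read a samples-by-metabolites matrix as tab-delimited text
#'
#' Samples are rows with a leading \code{sample_id} column; missing values
#' are written as \code{NA}.
#'
#' @param x numeric matrix (or \code{\link{metabolite_matrix}}, whose values
#'   are written).
#' @param path file path.
#' @return \code{write_matrix_tsv}: the path, invisibly;
#'   \code{read_matrix_tsv}: a numeric matrix with sample-id rownames.
#' @export
write_matrix_tsv <- function(x, path) {
  vals <- if (inherits(x, "metabolite_matrix")) x$values else x
  df <- data.frame(sample_id = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read GWAS summary statistics
#'
#' The layout is tab-delimited with header
#' \code{snp, effect_allele, other_allele, eaf, beta, se, pval, n}.
#'
#' @param gwas data frame in the summary-statistics layout.
#' @param path file path.
#' @return \code{read_gwas_tsv}: the data frame, validated.
#' @export
write_gwas_tsv <- function(gwas, path) {
  utils::write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
            "pval", "n")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("GWAS table ", path, " lacks columns: ", paste(miss, collapse = ", "))
  if (any(g$se <= 0, na.rm = TRUE)) stop("GWAS table has non-positive SEs")
  g
}

#' Read a pipeline configuration
#'
#' Accepts a YAML file path or an already-built list; see
#' \code{\link{run_pipeline}} for the recognised keys.
#'
#' @param config path to a YAML file, or a list.
#' @return The configuration list.
#' @export
read_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}
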