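#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of log-scale expression
#' values with features (HUGO gene symbols for mRNA, miRBase names for miRNA)
#' on rows and samples on columns. Identifiers must be unique and all values
#' finite.
#'
#' @param values Numeric matrix, features x samples.
#' @param feature_ids Character vector of row identifiers. Defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of column identifiers. Defaults to
#'   `colnames(values)`.
#' @return A numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values,
                              feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("expression matrix needs feature and sample identifiers")
  }
  if (length(feature_ids) != nrow(values) ||
      length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  rownames(values) <- as.character(feature_ids)
  colnames(values) <- as.character(sample_ids)
  check_expression_matrix(values)
  values
}

check_expression_matrix <- function(m) {
  if (anyDuplicated(rownames(m))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers and
#' feature identifiers in the first column. When several rows carry the same
#' feature identifier (multiple array probes for one gene or miRNA), the row
#' with the highest variance across samples is kept; variance ties are broken
#' by first occurrence.
#'
#' @param path Path to a TSV file.
#' @return A validated expression matrix (features x samples).
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a feature column and at least one sample")
  features <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 body[bad[1, 1], bad[1, 2]], features[bad[1, 1]],
                 samples[bad[1, 2]]))
  }
  dimnames(num) <- list(features, samples)
  if (anyDuplicated(features)) {
    v <- apply(num, 1, var)
    ord <- order(factor(features, levels = unique(features)), -v)
    num <- num[ord, , drop = FALSE]
    num <- num[!duplicated(rownames(num)), , drop = FALSE]
    num <- num[unique(features), , drop = FALSE]
  }
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param m Expression matrix.
#' @param path Output path.
#' @param feature_col Name for the first (feature id) column.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(m, path, feature_col = "feature_id") {
  check_expression_matrix(m)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-center an expression matrix
#'
#' Subtracts the per-feature (or per-sample) median, as commonly applied to
#' log-transformed microarray data before signature analysis.
#'
#' @param m Expression matrix.
#' @param axis Either `"feature"` (center each row) or `"sample"` (each
#'   column).
#' @return The centered matrix; the per-axis median of the result is 0.
#' @export
median_center <- function(m, axis = c("feature", "sample")) {
  axis <- match.arg(axis)
  check_expression_matrix(m)
  if (axis == "feature") {
    m - apply(m, 1, median)
  } else {
    sweep(m, 2, apply(m, 2, median))
  }
}

#' Bundle paired expression data and annotations into a cohort
#'
#' @param name Cohort name.
#' @param mrna mRNA expression matrix (genes x samples).
#' @param mirna Optional miRNA expression matrix; its samples must be a
#'   subset of the mRNA samples.
#' @param annotations Optional list with elements `family_of` and
#'   `cluster_of` (named character vectors, miRNA -> group id, `NA` for
#'   ungrouped) and `targets_of` (named list, miRNA -> character vector of
#'   predicted target genes).
#' @return An object of class `"mir_cohort"`.
#' @export
cohort <- function(name, mrna, mirna = NULL, annotations = list()) {
  check_expression_matrix(mrna)
  if (!is.null(mirna)) {
    check_expression_matrix(mirna)
    if (!all(colnames(mirna) %in% colnames(mrna))) {
      stop("miRNA samples must be a subset of mRNA samples")
    }
  }
  structure(list(name = name, mrna = mrna, mirna = mirna,
                 annotations = annotations),
            class = "mir_cohort")
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat(sprintf("cohort '%s': %d genes x %d samples", x$name,
              nrow(x$mrna), ncol(x$mrna)))
  if (!is.null(x$mirna)) {
    cat(sprintf("; %d miRNAs x %d samples", nrow(x$mirna), ncol(x$mirna)))
  }
  cat("\n")
  invisible(x)
}
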