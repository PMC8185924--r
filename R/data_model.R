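#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("CCD", "ICD", "NMC", "NMI", "UC")
COLON_GROUPS <- c("CCD", "NMC", "UC")

#' Construct a validated expression matrix
#'
#' An expression matrix is a dense numeric matrix of non-negative FPKM-scale
#' values with unique gene identifiers as row names and unique sample
#' identifiers as column names.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Optional character vector overriding `rownames(values)`.
#' @param sample_ids Optional character vector overriding `colnames(values)`.
#' @return A numeric matrix of class `expr_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Read an expression matrix from TSV
#'
#' The file must have a header row of sample ids with first header cell
#' `gene_id`, and one row per gene. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a gene_id column and >= 1 sample")
  gene_ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1)
  if (anyNA(num)) stop("non-numeric expression value in ", path)
  expression_matrix(num, gene_ids = gene_ids, sample_ids = colnames(vals))
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_matrix()]; values are printed at full precision so the
#' round trip is faithful.
#'
#' @param m Expression matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' Each sample carries one of five group labels (CCD, ICD, NMC, NMI, UC);
#' tissue is derived deterministically: CCD/NMC/UC are colonic biopsies,
#' ICD/NMI ileal.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param group Character vector of group labels.
#' @return A `data.frame` with columns sample_id, group, tissue.
#' @export
sample_metadata <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) stop("lengths differ")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  data.frame(sample_id = sample_id, group = group,
             tissue = ifelse(group %in% COLON_GROUPS, "colon", "ileum"),
             stringsAsFactors = FALSE)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return Metadata data.frame as from [sample_metadata()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df))) {
    stop("metadata needs sample_id and group columns")
  }
  sample_metadata(df$sample_id, df$group)
}

#' Write sample metadata to TSV
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta[, c("sample_id", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_meta_matches <- function(m, meta) {
  if (!setequal(colnames(m), meta$sample_id) ||
      length(meta$sample_id) != ncol(m)) {
    stop("metadata sample ids do not match matrix sample ids")
  }
}

group_samples <- function(meta, group) meta$sample_id[meta$group == group]

#' Analysis configuration
#'
#' Houses the pipeline constants: the confidence level of the non-overlap
#' filter (0.95), the significance threshold for differential expression
#' (p <= 0.05), the "no difference" threshold of the dual-threshold
#' specificity criteria (p > 0.1), the minimum-expression gene filter
#' (max FPKM >= 1), and the feature-selection settings (70/30 split,
#' 10-fold CV, 100 repeats, accuracy and AUC cutoffs of 0.8).
#'
#' @param ci_level Confidence level for group CIs.
#' @param alpha_sig Significance threshold for DEG calls.
#' @param alpha_ns "No difference" threshold (must be >= alpha_sig).
#' @param min_expression Minimum per-gene maximum FPKM to retain a gene.
#' @param split_fraction Training fraction of the stratified split.
#' @param cv_folds Number of cross-validation folds.
#' @param n_repeats Number of split/evaluate repetitions per gene.
#' @param acc_threshold Test-set accuracy cutoff for selection.
#' @param auc_threshold Test-set AUC cutoff for selection.
#' @param alpha_gate Alpha for the Shapiro/Levene branching gates.
#' @param seed Integer seed driving all randomized steps.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(ci_level = 0.95, alpha_sig = 0.05, alpha_ns = 0.1,
                            min_expression = 1.0, split_fraction = 0.7,
                            cv_folds = 10, n_repeats = 100,
                            acc_threshold = 0.8, auc_threshold = 0.8,
                            alpha_gate = 0.05, seed = 1L) {
  stopifnot(ci_level > 0, ci_level < 1,
            alpha_sig > 0, alpha_sig <= alpha_ns, alpha_ns < 1,
            split_fraction > 0, split_fraction < 1,
            cv_folds >= 2, n_repeats >= 1, min_expression >= 0)
  structure(list(ci_level = ci_level, alpha_sig = alpha_sig,
                 alpha_ns = alpha_ns, min_expression = min_expression,
                 split_fraction = split_fraction, cv_folds = as.integer(cv_folds),
                 n_repeats = as.integer(n_repeats),
                 acc_threshold = acc_threshold, auc_threshold = auc_threshold,
                 alpha_gate = alpha_gate, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Drop genes never expressed above a threshold
#'
#' A gene is retained iff its maximum FPKM across all samples is at least
#' `min_expression` (default 1). Idempotent; the identity when
#' `min_expression = 0` on non-negative data.
#'
#' @param m Expression matrix.
#' @param min_expression Non-negative threshold.
#' @return The filtered expression matrix (sample set unchanged).
#' @export
filter_low_expression <- function(m, min_expression = 1.0) {
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix")
  if (min_expression < 0) stop("min_expression must be >= 0")
  keep <- apply(m, 1, max) >= min_expression
  out <- m[keep, , drop = FALSE]
  class(out) <- class(m)
  out
}

#' Flag outlier samples by within-tissue correlation, with PCA coordinates
#'
#' A sample is flagged when its median Spearman correlation against the other
#' samples of the same tissue falls below `corr_threshold`. The first two
#' principal components of log2(FPKM + 1) are reported for inspection only;
#' flagging is purely correlation-based. Tissues with fewer than 3 samples
#' are skipped with a warning.
#'
#' @param m Expression matrix.
#' @param meta Sample metadata.
#' @param corr_threshold Median-correlation cutoff (default 0.7).
#' @return A list of class `qc_report`: `outlier_sample_ids`,
#'   `pc_coordinates` (data.frame sample_id/PC1/PC2), `median_correlation`
#'   (named numeric).
#' @export
detect_outliers <- function(m, meta, corr_threshold = 0.7) {
  check_meta_matches(m, meta)
  lg <- log2(t(m) + 1)                      # samples x genes
  pc <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  pcs <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  med_cor <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  outliers <- character(0)
  for (tis in unique(meta$tissue)) {
    ids <- meta$sample_id[meta$tissue == tis]
    if (length(ids) < 3) {
      warning("tissue '", tis, "' has < 3 samples; outlier flagging skipped")
      next
    }
    cc <- suppressWarnings(stats::cor(m[, ids, drop = FALSE],
                                      method = "spearman"))
    diag(cc) <- NA
    med <- apply(cc, 2, stats::median, na.rm = TRUE)
    med_cor[ids] <- med
    outliers <- c(outliers, ids[!is.na(med) & med < corr_threshold])
  }
  structure(list(
    outlier_sample_ids = sort(outliers),
    pc_coordinates = data.frame(sample_id = colnames(m),
                                PC1 = pcs[, 1],
                                PC2 = if (ncol(pcs) > 1) pcs[, 2] else NA_real_,
                                row.names = NULL, stringsAsFactors = FALSE),
    median_correlation = med_cor
  ), class = "qc_report")
}

#' Serialize a QC report to JSON
#' @param qc A `qc_report` from [detect_outliers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(list(
    outlier_sample_ids = qc$outlier_sample_ids,
    pc_coordinates = qc$pc_coordinates,
    median_correlation = as.list(qc$median_correlation)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
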