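#' Log-CPM normalization of a count matrix
#'
#' Scales each sample to counts per million and log-transforms:
#' `log2(1e6 * count / column_sum + 1)`. Zero counts map to 0 and doubling a
#' library leaves its normalized column unchanged.
#'
#' @param counts Gene-by-sample matrix of non-negative counts.
#' @param log Apply the log2(x + 1) transform (default TRUE); `FALSE` returns
#'   plain CPM.
#' @return Matrix of the same shape.
#' @export
normalize_counts <- function(counts, log = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero)) {
    stop(sprintf("zero-sum sample column(s): %s",
                 paste(colnames(counts)[zero] %||% which(zero),
                       collapse = ", ")), call. = FALSE)
  }
  cpm <- sweep(counts, 2, cs, "/") * 1e6
  if (log) log2(cpm + 1) else cpm
}

#' Select the most variable genes
#'
#' Ranks genes by the variance of their log-normalized values across all
#' samples and returns the top `n`; ties are broken by gene id so the
#' selection is deterministic and invariant to sample order.
#'
#' @param lognorm Gene-by-sample matrix of log-normalized expression.
#' @param n Number of genes to keep (default 200).
#' @return Character vector of gene ids (row names), or row indices when the
#'   matrix is unnamed.
#' @export
top_variable_genes <- function(lognorm, n = 200) {
  lognorm <- as.matrix(lognorm)
  n <- check_count(n, "n")
  if (n > nrow(lognorm)) stop("'n' exceeds the number of genes", call. = FALSE)
  v <- apply(lognorm, 1, stats::var)
  ids <- rownames(lognorm) %||% seq_len(nrow(lognorm))
  ids[order(-v, ids)][seq_len(n)]
}

#' Average expression replicates per condition
#'
#' @param lognorm Gene-by-sample matrix.
#' @param conditions Condition label per column (recycled from a sample
#'   sheet's `condition` column).
#' @return Gene-by-condition matrix of column means, condition order
#'   following first appearance.
#' @export
average_condition_replicates <- function(lognorm, conditions) {
  lognorm <- as.matrix(lognorm)
  if (length(conditions) != ncol(lognorm)) {
    stop("one condition label per sample column is required", call. = FALSE)
  }
  f <- factor(conditions, levels = unique(conditions))
  out <- vapply(levels(f), function(l) {
    rowMeans(lognorm[, f == l, drop = FALSE])
  }, numeric(nrow(lognorm)))
  out
}

#' Condition-to-condition Pearson correlation matrix
#'
#' Pairwise Pearson correlations between condition expression profiles over a
#' selected gene subset, after averaging replicates per condition. This is
#' the knockdown-to-knockdown similarity map of the transcriptome screen.
#'
#' @param lognorm Gene-by-sample log-normalized matrix.
#' @param conditions Condition label per sample column.
#' @param genes Optional gene subset (default: all rows).
#' @return A symmetric correlation matrix with unit diagonal, class
#'   `condition_correlation`, carrying attribute `modality = "expression"`.
#'   Constant conditions yield `NA` rows/columns with a warning.
#' @export
condition_correlation <- function(lognorm, conditions, genes = NULL) {
  avg <- average_condition_replicates(lognorm, conditions)
  if (!is.null(genes)) avg <- avg[genes, , drop = FALSE]
  if (ncol(avg) < 2) stop("need at least 2 conditions", call. = FALSE)
  sds <- apply(avg, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("constant condition profile(s): %s",
                    paste(colnames(avg)[sds == 0], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(avg))
  diag(r) <- 1
  structure(r, class = c("condition_correlation", class(r)),
            modality = "expression")
}

#' High-content profile correlation matrix
#'
#' Pairwise Pearson correlations between targets' feature Z-profiles — the
#' imaging-modality counterpart of [condition_correlation()].
#'
#' @param profiles A `feature_profiles` object or target-by-feature matrix.
#' @param targets Optional subset of targets.
#' @return Symmetric correlation matrix of class `condition_correlation`
#'   with attribute `modality = "high_content"`.
#' @export
profile_correlation <- function(profiles, targets = NULL) {
  mat <- if (inherits(profiles, "feature_profiles")) profiles$profiles
         else as.matrix(profiles)
  if (!is.null(targets)) mat <- mat[targets, , drop = FALSE]
  if (nrow(mat) < 2) stop("need at least 2 targets", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(mat), use = "pairwise.complete.obs"))
  diag(r) <- 1
  structure(r, class = c("condition_correlation", class(r)),
            modality = "high_content")
}

#' Cross-modal concordance of condition pairs
#'
#' Joins the expression and high-content correlation matrices over their
#' shared conditions and reports, per unordered pair, the correlation in each
#' modality. Pairs exceeding both thresholds are flagged: such pairs behave
#' alike in colony phenotype *and* transcriptome, the signature used to
#' nominate functionally interacting genes.
#'
#' @param expr_corr Correlation matrix from [condition_correlation()].
#' @param feature_corr Correlation matrix from [profile_correlation()].
#' @param expr_threshold,feature_threshold Flagging thresholds (default 0.5).
#' @return Data frame with one row per unordered shared pair: `a`, `b`,
#'   `r_expression`, `r_high_content`, `concordance` (product of the two,
#'   floored at 0 when signs disagree) and `flagged`; sorted by decreasing
#'   concordance.
#' @export
crossmodal_concordance <- function(expr_corr, feature_corr,
                                   expr_threshold = 0.5,
                                   feature_threshold = 0.5) {
  shared <- intersect(colnames(expr_corr), colnames(feature_corr))
  if (length(shared) < 2) {
    stop("expression and high-content matrices share fewer than 2 conditions",
         call. = FALSE)
  }
  idx <- utils::combn(shared, 2)
  re <- expr_corr[cbind(idx[1, ], idx[2, ])]
  rf <- feature_corr[cbind(idx[1, ], idx[2, ])]
  conc <- ifelse(re > 0 & rf > 0, re * rf, 0)
  out <- data.frame(a = idx[1, ], b = idx[2, ],
                    r_expression = re, r_high_content = rf,
                    concordance = conc,
                    flagged = re >= expr_threshold & rf >= feature_threshold,
                    stringsAsFactors = FALSE)
  out[order(-out$concordance), , drop = FALSE]
}
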