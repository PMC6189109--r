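#' Read a log2 expression matrix and sample labels
#'
#' The matrix is a TSV with gene identifiers in the first column and one
#' column per sample (header row); values are log2 intensities. Labels are a
#' two-column TSV (sample_id, label) with labels in \{case, control\}.
#'
#' @param path TSV file path.
#' @return \code{readExpressionMatrix}: numeric matrix (genes x samples);
#'   \code{readSampleLabels}: named character vector of labels.
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path))
        stop("expression matrix not found: ", path)
    df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
}

#' @rdname readExpressionMatrix
#' @export
readSampleLabels <- function(path) {
    if (!file.exists(path))
        stop("label file not found: ", path)
    df <- utils::read.delim(path, header = TRUE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("label file must have two columns: sample_id, label")
    setNames(df[[2L]], df[[1L]])
}

#' Screen for commonly upregulated genes
#'
#' For every gene of a log2 expression matrix, computes the case-vs-control
#' fold change as the difference of group means in log2 space and an
#' unpaired two-sided t-test (Welch by default; set \code{var_equal = TRUE}
#' for the pooled-variance test). A gene is selected when its fold change
#' strictly exceeds \code{log2(fold)} and its p-value is strictly below
#' \code{alpha}; results are sorted by descending fold change. No
#' multiple-testing correction is applied (selection is on raw p-values).
#'
#' Genes with zero variance in both groups have no defined t statistic;
#' they are reported with \code{p = NA}, left unselected, and counted in a
#' warning.
#'
#' @param mat numeric matrix, genes x samples, log2 scale.
#' @param labels character vector of \code{"case"}/\code{"control"} labels,
#'   either named by sample or in column order; each group needs >= 2
#'   samples.
#' @param fold linear fold-change cutoff (default 1.5, strict).
#' @param alpha p-value cutoff (default 0.01, strict).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame (gene, log2fc, t, p, selected) sorted by descending
#'   log2fc.
#' @export
screenUpregulated <- function(mat, labels, fold = 1.5, alpha = 0.01,
                              var_equal = FALSE) {
    mat <- as.matrix(mat)
    if (!is.null(names(labels))) {
        if (!all(colnames(mat) %in% names(labels)))
            stop("missing labels for samples: ",
                 paste(setdiff(colnames(mat), names(labels)),
                       collapse = ", "))
        labels <- labels[colnames(mat)]
    }
    if (length(labels) != ncol(mat))
        stop("need one label per sample column")
    if (!all(labels %in% c("case", "control")))
        stop("labels must be 'case' or 'control'")
    case <- mat[, labels == "case", drop = FALSE]
    ctrl <- mat[, labels == "control", drop = FALSE]
    if (ncol(case) < 2L || ncol(ctrl) < 2L)
        stop("each group needs at least 2 samples")
    log2fc <- rowMeans(case) - rowMeans(ctrl)
    tp <- vapply(seq_len(nrow(mat)), function(i) {
        res <- tryCatch(
            stats::t.test(case[i, ], ctrl[i, ], var.equal = var_equal),
            error = function(e) NULL)
        if (is.null(res)) c(NA_real_, NA_real_)
        else c(unname(res$statistic), res$p.value)
    }, numeric(2L))
    p <- tp[2L, ]
    if (anyNA(p))
        warning(sum(is.na(p)),
                " gene(s) with zero variance in both groups: ",
                "p undefined, reported unselected")
    selected <- !is.na(p) & p < alpha & log2fc > log2(fold)
    out <- data.frame(gene = rownames(mat), log2fc = log2fc, t = tp[1L, ],
                      p = p, selected = selected)
    rownames(out) <- NULL
    out[order(-out$log2fc), , drop = FALSE]
}
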