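#' Per-gene intron retention table
#'
#' Aggregates junction counts to one IR record per gene and sample. The
#' gene-level IR coefficient is the ratio of summed counts,
#' \code{ir = a_total / b_total} with \code{a_total} the sum of
#' donor + acceptor (exon-intron) reads over the gene's junctions and
#' \code{b_total} the summed exon-exon reads. Summing before dividing keeps
#' the estimate stable when individual junctions have few reads; per-junction
#' ratios remain available from [countsTable()] for inspection. Degenerate
#' cases are encoded in \code{status}: \code{"infinite"} when
#' \code{a_total > 0} and \code{b_total = 0} (retention with no spliced
#' evidence), \code{"undefined"} when both are zero; \code{ir} is \code{NA}
#' for both.
#'
#' @param countSet a [JunctionCountSet-class] from [countJunctions()].
#' @param catalog the [JunctionCatalog-class] the counts were made against.
#' @return a data.frame with columns gene_id, sample_id, a_total, b_total,
#'   ir, status, and rpkm (NA when expression was not quantified).
#' @export
geneIRTable <- function(countSet, catalog) {
    stopifnot(is(countSet, "JunctionCountSet"), is(catalog, "JunctionCatalog"))
    cnt <- as.data.frame(countsTable(countSet))
    intr <- intronRanges(catalog)
    cnt$gene_id <- intr$gene_id[match(cnt$junction_id, intr$junction_id)]
    if (anyNA(cnt$gene_id))
        stop("counts contain junctions absent from the catalog")
    key <- interaction(cnt$gene_id, cnt$sample_id, drop = TRUE)
    a <- tapply(cnt$a_donor + cnt$a_acceptor, key, sum)
    b <- tapply(cnt$b, key, sum)
    first <- tapply(seq_len(nrow(cnt)), key, `[`, 1L)
    out <- data.frame(gene_id = cnt$gene_id[first],
                      sample_id = cnt$sample_id[first],
                      a_total = as.integer(a), b_total = as.integer(b))
    out$ir <- ifelse(out$b_total > 0, out$a_total / out$b_total, NA_real_)
    out$status <- ifelse(out$b_total > 0, "ok",
                         ifelse(out$a_total > 0, "infinite", "undefined"))
    gc <- as.data.frame(geneCountsTable(countSet))
    if (nrow(gc)) {
        m <- match(paste(out$gene_id, out$sample_id),
                   paste(gc$gene_id, gc$sample_id))
        out$rpkm <- gc$rpkm[m]
    } else {
        out$rpkm <- NA_real_
    }
    out[order(out$gene_id, out$sample_id), , drop = FALSE]
}

#' Flag high-confidence genes
#'
#' A gene is high confidence when, averaged over the control replicates, it
#' has at least \code{min_junction_reads} total junction reads
#' (a_total + b_total) and control RPKM at or above \code{min_rpkm}. Both
#' thresholds are inclusive.
#'
#' @param geneTable data.frame from [geneIRTable()].
#' @param control_samples character vector of control sample_ids (>= 1).
#' @param min_junction_reads inclusive mean junction-read threshold
#'   (default 10).
#' @param min_rpkm inclusive mean control RPKM threshold (default 100).
#' @return \code{geneTable} with a logical \code{high_confidence} column
#'   (constant within gene).
#' @export
filterHighConfidence <- function(geneTable, control_samples,
                                 min_junction_reads = 10,
                                 min_rpkm = 100) {
    if (length(control_samples) == 0L)
        stop("no control samples given")
    ctrl <- geneTable[geneTable$sample_id %in% control_samples, ,
                      drop = FALSE]
    if (nrow(ctrl) == 0L)
        stop("none of the control samples are present in the table")
    jr <- tapply(ctrl$a_total + ctrl$b_total, ctrl$gene_id, mean)
    rp <- tapply(ctrl$rpkm, ctrl$gene_id, mean)
    hc <- jr >= min_junction_reads & !is.na(rp) & rp >= min_rpkm
    geneTable$high_confidence <- as.logical(hc[geneTable$gene_id])
    geneTable$high_confidence[is.na(geneTable$high_confidence)] <- FALSE
    geneTable
}

#' Differential intron retention between conditions
#'
#' For every high-confidence gene, IR is computed per replicate, averaged
#' within each condition, and the knockdown/control fold
#' \code{ir_fold = ir_kd / ir_ctrl} is tested against \code{threshold}
#' (strict inequality): genes with fold above it are flagged as aberrant
#' intron retention. Only retention gains are flagged; decreases are
#' reported unflagged. Genes with an infinite replicate IR (spliced count 0)
#' in either condition, without any defined replicate, or with
#' \code{ir_ctrl = 0} are excluded from the fold computation and reported
#' separately.
#'
#' @param geneTable data.frame from [geneIRTable()], optionally already
#'   carrying a \code{high_confidence} column (otherwise
#'   [filterHighConfidence()] is applied with default thresholds).
#' @param control_samples,kd_samples sample_id vectors for the two
#'   conditions (each >= 1 replicate).
#' @param threshold fold cutoff for calling aberrant retention
#'   (default 1.15, strict).
#' @return list with \code{table} (gene_id, ir_ctrl, ir_kd, ir_fold,
#'   aberrant), \code{excluded} (gene_id, reason), and \code{summary}
#'   (n_high_confidence, n_evaluated, n_aberrant, fraction_aberrant =
#'   n_aberrant / n_high_confidence).
#' @export
differentialIR <- function(geneTable, control_samples, kd_samples,
                           threshold = 1.15) {
    if (length(control_samples) < 1L || length(kd_samples) < 1L)
        stop("both conditions need at least one replicate")
    if (!"high_confidence" %in% colnames(geneTable))
        geneTable <- filterHighConfidence(geneTable, control_samples)
    hcGenes <- unique(geneTable$gene_id[geneTable$high_confidence])
    if (length(hcGenes) == 0L)
        stop("no high-confidence genes to evaluate")
    condMean <- function(samples) {
        sub <- geneTable[geneTable$sample_id %in% samples &
                         geneTable$gene_id %in% hcGenes, , drop = FALSE]
        inf <- tapply(sub$status == "infinite", sub$gene_id, any)
        mu <- tapply(ifelse(sub$status == "ok", sub$ir, NA_real_),
                     sub$gene_id, mean, na.rm = TRUE)
        list(mu = mu, inf = inf)
    }
    cc <- condMean(control_samples)
    kk <- condMean(kd_samples)
    genes <- sort(hcGenes)
    mu_c <- cc$mu[genes]
    mu_k <- kk$mu[genes]
    inf_any <- (cc$inf[genes] %in% TRUE) | (kk$inf[genes] %in% TRUE)
    reason <- rep(NA_character_, length(genes))
    reason[is.nan(mu_c) | is.na(mu_c) | is.nan(mu_k) | is.na(mu_k)] <-
        "undefined_ir"
    reason[inf_any] <- "infinite_ir"
    reason[is.na(reason) & mu_c == 0] <- "zero_control_ir"
    ok <- is.na(reason)
    if (!any(ok))
        stop("no genes with finite IR in both conditions")
    tab <- data.frame(gene_id = genes[ok],
                      ir_ctrl = unname(mu_c[ok]),
                      ir_kd = unname(mu_k[ok]))
    tab$ir_fold <- tab$ir_kd / tab$ir_ctrl
    tab$aberrant <- tab$ir_fold > threshold
    excluded <- data.frame(gene_id = genes[!ok], reason = reason[!ok])
    summary <- list(n_high_confidence = length(genes),
                    n_evaluated = nrow(tab),
                    n_aberrant = sum(tab$aberrant),
                    fraction_aberrant = sum(tab$aberrant) / length(genes))
    list(table = tab, excluded = excluded, summary = summary)
}

#' Global shift of the IR distribution (two-sample KS)
#'
#' Two-sided two-sample Kolmogorov-Smirnov comparison of the control and
#' knockdown IR coefficient vectors, with asymptotic p-value, plus the two
#' empirical cumulative distribution functions tabulated for plotting. A
#' rightward shift of the knockdown ECDF (knockdown stochastically larger)
#' indicates global pre-mRNA accumulation.
#'
#' @param ir_ctrl,ir_kd numeric vectors of per-gene IR coefficients; each
#'   must contain at least 2 finite values (others are dropped).
#' @return list with \code{statistic} (D), \code{p.value}, and \code{ecdf},
#'   a data.frame (value, ecdf_ctrl, ecdf_kd) over the pooled values.
#' @export
ksShift <- function(ir_ctrl, ir_kd) {
    x <- ir_ctrl[is.finite(ir_ctrl)]
    y <- ir_kd[is.finite(ir_kd)]
    if (length(x) < 2L || length(y) < 2L)
        stop("each condition needs at least 2 finite IR values")
    kt <- suppressWarnings(
        stats::ks.test(y, x, alternative = "two.sided", exact = FALSE))
    v <- sort(unique(c(x, y)))
    ecdfTab <- data.frame(value = v,
                          ecdf_ctrl = stats::ecdf(x)(v),
                          ecdf_kd = stats::ecdf(y)(v))
    list(statistic = unname(kt$statistic), p.value = kt$p.value,
         ecdf = ecdfTab)
}

#' Splicing efficiency
#'
#' Ratio of spliced product to total (spliced + unspliced) product, as
#' quantified from a minigene or RT-PCR readout. Vectorized.
#'
#' @param spliced,unspliced nonnegative quantifications.
#' @return numeric in \[0, 1\].
#' @export
splicingEfficiency <- function(spliced, unspliced) {
    if (any(spliced < 0) || any(unspliced < 0))
        stop("spliced and unspliced must be nonnegative")
    tot <- spliced + unspliced
    if (any(tot == 0))
        stop("spliced + unspliced must be > 0")
    spliced / tot
}

#' Relative expression by the 2^-ddCt method
#'
#' \code{2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))}: target
#' gene Ct normalized to a reference gene (e.g. ACTIN) in the sample and in
#' the calibrator. Vectorized.
#'
#' @param ct_target_s,ct_ref_s target and reference Ct in the sample.
#' @param ct_target_c,ct_ref_c target and reference Ct in the calibrator.
#' @return relative expression (1 = no change).
#' @export
ddct <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
    ct <- c(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c)
    if (any(!is.finite(ct)))
        stop("all Ct values must be finite")
    2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))
}
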