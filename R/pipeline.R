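## Stage runners: each writes its declared outputs plus a run manifest, so
## a shell session (or the junctionIR script in exec/) can chain
## simulate -> catalog -> count -> ir -> diff with files as the interface.

#' Write a run manifest
#'
#' Every stage runner records the command, all materialized parameter
#' values, md5 checksums of its inputs, the package version and a
#' timestamp next to its outputs, so that a result directory is
#' self-describing.
#'
#' @param outdir output directory.
#' @param command stage name.
#' @param params named list of parameter values.
#' @param inputs character vector of input file paths.
#' @return the manifest path, invisibly.
#' @export
writeRunManifest <- function(outdir, command, params, inputs = character()) {
    inputs <- inputs[file.exists(inputs)]
    manifest <- list(
        command = command,
        parameters = params,
        input_md5 = as.list(tools::md5sum(inputs)),
        tool = "junctionIR",
        version = as.character(utils::packageVersion("junctionIR")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    path <- file.path(outdir, paste0(command, "_manifest.json"))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Pipeline stage runners
#'
#' File-level entry points for each stage of the intron-retention pipeline;
#' the \code{junctionIR} script in the package's \code{exec/} directory
#' exposes them as shell subcommands. All defaults mirror the analysis
#' parameters: overhang 6 nt, min_mapq 10, high-confidence filter (mean >=
#' 10 junction reads, RPKM >= 100 in controls), differential IR fold
#' threshold 1.15, screen fold 1.5 at alpha 0.01. \code{runDiff} called on
#' count outputs equals \code{runIR} followed by \code{runDiff} on the IR
#' table.
#'
#' @param outdir output directory, created if needed.
#' @param seed integer seed (simulate).
#' @param ... passed through to [simConfig()].
#' @return each runner returns its main result invisibly (paths or tables).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(outdir, seed, ...) {
    config <- simConfig(seed = seed, ...)
    res <- simulateDataset(config, outdir)
    writeRunManifest(outdir, "simulate", unclass(config))
    invisible(res)
}

#' @rdname pipeline
#' @param gtf GTF annotation path.
#' @param overhang junction anchor in nt (default 6).
#' @export
runCatalog <- function(gtf, outdir, overhang = 6L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    models <- readGeneModels(gtf)
    catalog <- buildJunctionCatalog(models, overhang = overhang)
    path <- file.path(outdir, "junction_catalog.tsv")
    writeJunctionCatalog(catalog, path)
    writeRunManifest(outdir, "catalog",
                     list(gtf = gtf, overhang = overhang), gtf)
    invisible(list(catalog = catalog, path = path))
}

#' @rdname pipeline
#' @param alignments character vector of SAM/BAM paths, named by sample id.
#' @param catalog_file TSV written by [writeJunctionCatalog()].
#' @param min_mapq minimum mapping quality (default 10).
#' @export
runCount <- function(alignments, catalog_file, gtf, outdir,
                     min_mapq = 10L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    catalog <- readJunctionCatalog(catalog_file)
    models <- readGeneModels(gtf)
    cs <- countJunctions(alignments, catalog, models = models,
                         min_mapq = min_mapq)
    countsPath <- file.path(outdir, "junction_counts.tsv")
    utils::write.table(as.data.frame(countsTable(cs)), countsPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genePath <- file.path(outdir, "gene_expression.tsv")
    gc <- as.data.frame(geneCountsTable(cs))
    gc$total_mapped <- totalMapped(cs)[gc$sample_id]
    utils::write.table(gc, genePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeRunManifest(outdir, "count",
                     list(alignments = as.list(alignments),
                          catalog = catalog_file, gtf = gtf,
                          min_mapq = min_mapq),
                     c(alignments, catalog_file, gtf))
    invisible(list(countSet = cs, counts = countsPath, genes = genePath))
}

#' @rdname pipeline
#' @param counts_file junction_counts.tsv from \code{runCount}.
#' @param genes_file gene_expression.tsv from \code{runCount}.
#' @export
runIR <- function(counts_file, genes_file, catalog_file, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    catalog <- readJunctionCatalog(catalog_file)
    cs <- .countSetFromFiles(counts_file, genes_file)
    tab <- geneIRTable(cs, catalog)
    path <- file.path(outdir, "gene_ir.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeRunManifest(outdir, "ir",
                     list(counts = counts_file, genes = genes_file,
                          catalog = catalog_file),
                     c(counts_file, genes_file, catalog_file))
    invisible(list(table = tab, path = path))
}

#' @rdname pipeline
#' @param ir_file gene_ir.tsv from \code{runIR}; alternatively give
#'   \code{counts_file}/\code{genes_file}/\code{catalog_file} to chain the
#'   IR stage implicitly.
#' @param control_samples,kd_samples sample id vectors.
#' @param ir_fold differential IR threshold (default 1.15, strict).
#' @param min_junction_reads,min_rpkm high-confidence filter thresholds.
#' @export
runDiff <- function(outdir, control_samples, kd_samples,
                    ir_file = NULL, counts_file = NULL, genes_file = NULL,
                    catalog_file = NULL, ir_fold = 1.15,
                    min_junction_reads = 10, min_rpkm = 100) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    inputs <- c(ir_file, counts_file, genes_file, catalog_file)
    if (!is.null(ir_file)) {
        tab <- utils::read.delim(ir_file, stringsAsFactors = FALSE)
    } else {
        if (is.null(counts_file) || is.null(genes_file) ||
            is.null(catalog_file))
            stop("give either ir_file or counts/genes/catalog files")
        catalog <- readJunctionCatalog(catalog_file)
        cs <- .countSetFromFiles(counts_file, genes_file)
        tab <- geneIRTable(cs, catalog)
    }
    tab <- filterHighConfidence(tab, control_samples,
                                min_junction_reads = min_junction_reads,
                                min_rpkm = min_rpkm)
    diff <- differentialIR(tab, control_samples, kd_samples,
                           threshold = ir_fold)
    ks <- ksShift(diff$table$ir_ctrl, diff$table$ir_kd)
    utils::write.table(diff$table,
                       file.path(outdir, "differential_ir.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ks$ecdf, file.path(outdir, "ir_ecdf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- c(list(n_genes = length(unique(tab$gene_id)),
                      n_samples = length(unique(tab$sample_id))),
                 diff$summary,
                 list(ks_D = ks$statistic, ks_p = ks$p.value))
    jsonlite::write_json(summary, file.path(outdir, "ir_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeRunManifest(outdir, "diff",
                     list(control_samples = as.list(control_samples),
                          kd_samples = as.list(kd_samples),
                          ir_fold = ir_fold,
                          min_junction_reads = min_junction_reads,
                          min_rpkm = min_rpkm),
                     inputs)
    invisible(list(differential = diff, ks = ks, summary = summary))
}

#' @rdname pipeline
#' @param matrix_file log2 expression matrix TSV.
#' @param labels_file two-column sample label TSV.
#' @param fold,alpha screen thresholds (defaults 1.5 and 0.01, strict).
#' @export
runScreen <- function(matrix_file, labels_file, outdir, fold = 1.5,
                      alpha = 0.01) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    mat <- readExpressionMatrix(matrix_file)
    labels <- readSampleLabels(labels_file)
    res <- screenUpregulated(mat, labels, fold = fold, alpha = alpha)
    path <- file.path(outdir, "screen.tsv")
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeRunManifest(outdir, "screen",
                     list(matrix = matrix_file, labels = labels_file,
                          fold = fold, alpha = alpha),
                     c(matrix_file, labels_file))
    invisible(list(table = res, path = path))
}

#' @rdname pipeline
#' @param fasta genome FASTA path.
#' @param consensus,branch_pos,window,min_score see [scanBranchSite()].
#' @export
runBranch <- function(catalog_file, fasta, outdir,
                      consensus = "UCCUGNC", branch_pos = 6L,
                      window = 100L, min_score = nchar(consensus)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    catalog <- readJunctionCatalog(catalog_file)
    hits <- scanCatalogBranchSites(catalog, fasta, consensus = consensus,
                                   branch_pos = branch_pos,
                                   window = window, min_score = min_score)
    path <- file.path(outdir, "branch_sites.tsv")
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeRunManifest(outdir, "branch",
                     list(catalog = catalog_file, fasta = fasta,
                          consensus = consensus, branch_pos = branch_pos,
                          window = window, min_score = min_score),
                     c(catalog_file, fasta))
    invisible(list(table = hits, path = path))
}

.countSetFromFiles <- function(counts_file, genes_file) {
    cnt <- utils::read.delim(counts_file, stringsAsFactors = FALSE)
    gc <- utils::read.delim(genes_file, stringsAsFactors = FALSE)
    tm <- gc[!duplicated(gc$sample_id), c("sample_id", "total_mapped")]
    samples <- unique(cnt$sample_id)
    new("JunctionCountSet",
        counts = DataFrame(cnt),
        geneCounts = DataFrame(gc[, c("gene_id", "sample_id",
                                      "mature_count", "rpkm")]),
        totalMapped = setNames(tm$total_mapped, tm$sample_id),
        samples = samples)
}
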