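#' Read gene models from a GTF annotation
#'
#' Parses a GTF file (Ensembl/GENCODE dialect; \code{gene_id} and
#' \code{transcript_id} attributes required on exon records) into a
#' [GeneModels-class] object. GTF coordinates are 1-based inclusive and are
#' kept in that convention inside GRanges; 0-based half-open conversion
#' happens only when the junction catalog is exported as TSV/BED.
#'
#' Exons within a transcript must be non-overlapping; the merged exon length
#' recorded per gene is the length of the union of all its exon intervals
#' over all transcripts (the kilobase denominator of RPKM).
#'
#' @param path path to a GTF file.
#' @return a [GeneModels-class] object.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "100", "200", ".", "+", ".",
#'                  'gene_id "g1"; transcript_id "g1.t1";', sep = "\t"), gtf)
#' gm <- readGeneModels(gtf)
#' mergedExonLength(gm)  # 101 nt
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path))
        stop("GTF file not found: ", path)
    raw <- readLines(path)
    body <- which(!startsWith(raw, "#") & nzchar(raw))
    if (length(body)) {
        nf <- vapply(strsplit(raw[body], "\t", fixed = TRUE), length, 0L)
        if (any(nf < 9L))
            stop("malformed GTF record at line ", body[which(nf < 9L)[1L]],
                 ": expected 9 tab-separated fields, found ",
                 nf[which(nf < 9L)[1L]])
    }
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(ex) == 0L)
        stop("no exon records in GTF: ", path)
    if (is.null(ex$gene_id) || anyNA(ex$gene_id))
        stop("exon record(s) without a gene_id attribute")
    if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
        stop("exon record(s) without a transcript_id attribute (",
             sum(is.na(ex$transcript_id)), " records)")
    ex <- GRanges(seqnames(ex), IRanges(start(ex), end(ex)),
                  strand = strand(ex),
                  gene_id = as.character(ex$gene_id),
                  transcript_id = as.character(ex$transcript_id))
    ex <- ex[order(ex$gene_id, ex$transcript_id, start(ex))]
    txkey <- paste(ex$gene_id, ex$transcript_id, sep = "\r")
    bytx <- S4Vectors::split(ex, factor(txkey, levels = unique(txkey)))
    if (!all(GenomicRanges::isDisjoint(bytx))) {
        bad <- names(bytx)[!GenomicRanges::isDisjoint(bytx)][1L]
        stop("overlapping exons within transcript ",
             sub(".*\r", "", bad), " of gene ", sub("\r.*", "", bad))
    }
    gid <- factor(ex$gene_id, levels = unique(ex$gene_id))
    bygene <- S4Vectors::split(ex, gid)
    chrom <- vapply(bygene, function(g)
        as.character(seqnames(g)[1L]), "")
    str1 <- vapply(bygene, function(g) {
        s <- unique(as.character(strand(g)))
        if (length(s) != 1L)
            stop("gene ", g$gene_id[1L], " has exons on both strands")
        s
    }, "")
    mlen <- vapply(bygene, function(g)
        sum(width(reduce(g, ignore.strand = TRUE))), 0L)
    genes <- DataFrame(gene_id = levels(gid), chrom = chrom, strand = str1,
                       merged_exon_length = as.integer(mlen),
                       row.names = levels(gid))
    new("GeneModels", exons = ex, genes = genes)
}

#' Build the junction catalog from gene models
#'
#' Derives one junction record per distinct (gene, intron interval), where an
#' intron is a gap between two consecutive exons in at least one transcript of
#' the gene. Intron chains shared by several transcripts are deduplicated;
#' junctions from distinct genes with identical coordinates are kept
#' separately but flagged \code{ambiguous}.
#'
#' A boundary is marked non-measurable when any of the first \code{overhang}
#' intronic bases adjacent to it are exonic in any overlapping annotated
#' transcript (any gene): a read crossing such a boundary cannot be
#' distinguished from an exonic read of the other isoform, so it must not be
#' taken as retention evidence. Donor is the 5' splice site in transcript
#' orientation (left genomic boundary on the + strand, right on the - strand).
#'
#' @param models a [GeneModels-class] object.
#' @param overhang integer >= 1; minimum anchor in nt (default 6).
#' @return a [JunctionCatalog-class] object.
#' @export
buildJunctionCatalog <- function(models, overhang = 6L) {
    stopifnot(is(models, "GeneModels"))
    overhang <- as.integer(overhang)
    if (length(overhang) != 1L || is.na(overhang) || overhang < 1L)
        stop("overhang must be a single integer >= 1")
    ex <- exonRanges(models)
    if (length(ex) == 0L)
        return(new("JunctionCatalog", introns = .emptyIntrons(),
                   overhang = overhang))
    txkey <- paste(ex$gene_id, ex$transcript_id, sep = "\r")
    bytx <- S4Vectors::split(ex, factor(txkey, levels = unique(txkey)))
    ## per-transcript introns = gaps between consecutive exons
    rng <- unlist(range(bytx))
    intr <- IRanges::psetdiff(rng, bytx)
    ngap <- S4Vectors::elementNROWS(intr)
    gene <- rep(sub("\r.*", "", names(bytx)), ngap)
    intr <- unlist(intr, use.names = FALSE)
    if (length(intr) == 0L)
        return(new("JunctionCatalog", introns = .emptyIntrons(),
                   overhang = overhang))
    ## deduplicate by (gene, coords)
    key <- paste(gene, as.character(seqnames(intr)), start(intr), end(intr))
    keep <- !duplicated(key)
    intr <- intr[keep]
    gene <- gene[keep]
    o <- order(gene, start(intr))
    intr <- intr[o]
    gene <- gene[o]
    ## identical coordinates in more than one gene -> ambiguous
    ckey <- paste(as.character(seqnames(intr)), start(intr), end(intr))
    ambiguous <- ckey %in% ckey[duplicated(ckey)]
    ## boundary masking against all annotated exons (any gene/transcript)
    wl <- pmin(overhang, width(intr))
    leftw <- GRanges(seqnames(intr), IRanges(start(intr), width = wl))
    rightw <- GRanges(seqnames(intr),
                      IRanges(end(intr) - wl + 1L, end(intr)))
    leftMasked <- overlapsAny(leftw, ex, ignore.strand = TRUE)
    rightMasked <- overlapsAny(rightw, ex, ignore.strand = TRUE)
    minus <- as.character(strand(intr)) == "-"
    donor_measurable <- ifelse(minus, !rightMasked, !leftMasked)
    acceptor_measurable <- ifelse(minus, !leftMasked, !rightMasked)
    mcols(intr) <- DataFrame(
        junction_id = paste0(gene, ":", as.character(seqnames(intr)), ":",
                             start(intr) - 1L, "-", end(intr)),
        gene_id = gene,
        donor_measurable = donor_measurable,
        acceptor_measurable = acceptor_measurable,
        ambiguous = ambiguous)
    new("JunctionCatalog", introns = intr, overhang = overhang)
}

.emptyIntrons <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(junction_id = character(), gene_id = character(),
                           donor_measurable = logical(),
                           acceptor_measurable = logical(),
                           ambiguous = logical())
    gr
}

#' Write and read a junction catalog as BED-like TSV
#'
#' The export uses 0-based half-open intron coordinates (BED convention):
#' \code{intron_start} is the 0-based first intronic base, \code{intron_end}
#' the exclusive end. A \code{#overhang=} header line preserves the anchoring
#' parameter so that the round trip reproduces the catalog exactly.
#'
#' @param catalog a [JunctionCatalog-class] object.
#' @param path output (input) TSV path.
#' @return \code{writeJunctionCatalog} returns \code{path} invisibly;
#'   \code{readJunctionCatalog} returns a [JunctionCatalog-class].
#' @export
writeJunctionCatalog <- function(catalog, path) {
    stopifnot(is(catalog, "JunctionCatalog"))
    ir <- intronRanges(catalog)
    df <- data.frame(junction_id = ir$junction_id,
                     gene_id = ir$gene_id,
                     chrom = as.character(seqnames(ir)),
                     intron_start = start(ir) - 1L,
                     intron_end = end(ir),
                     strand = as.character(strand(ir)),
                     donor_measurable = ir$donor_measurable,
                     acceptor_measurable = ir$acceptor_measurable,
                     ambiguous = ir$ambiguous)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#overhang=", junctionOverhang(catalog)), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeJunctionCatalog
#' @export
readJunctionCatalog <- function(path) {
    if (!file.exists(path))
        stop("catalog file not found: ", path)
    first <- readLines(path, n = 1L)
    overhang <- if (startsWith(first, "#overhang="))
        as.integer(sub("#overhang=", "", first)) else 6L
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom,
                  IRanges(df$intron_start + 1L, df$intron_end),
                  strand = df$strand)
    mcols(gr) <- DataFrame(junction_id = df$junction_id,
                           gene_id = df$gene_id,
                           donor_measurable = df$donor_measurable,
                           acceptor_measurable = df$acceptor_measurable,
                           ambiguous = df$ambiguous)
    new("JunctionCatalog", introns = gr, overhang = overhang)
}
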