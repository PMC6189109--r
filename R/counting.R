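#' @importFrom GenomicAlignments readGAlignments grglist
#' @importFrom Rsamtools asBam BamFile ScanBamParam scanBamFlag
NULL

## Convert a text SAM to a temporary BAM if needed; BAM paths pass through.
.ensureBam <- function(path) {
    if (!file.exists(path))
        stop("alignment file not found: ", path)
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile()
        asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
    } else {
        path
    }
}

## Read primary, mapped, non-duplicate alignments with mapq and qname.
.readPrimary <- function(path) {
    bam <- .ensureBam(path)
    param <- ScanBamParam(
        flag = scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE,
                           isDuplicate = FALSE),
        what = c("mapq", "qname"))
    readGAlignments(BamFile(bam), param = param)
}

## Reference-contiguous aligned blocks (split at N gaps only) plus the read
## index of each block. Blocks are in ascending reference order per read.
.alignedBlocks <- function(gal) {
    bl <- grglist(gal, order.as.in.query = FALSE)
    list(blocks = unlist(bl, use.names = FALSE),
         read = rep(seq_along(gal), S4Vectors::elementNROWS(bl)))
}

#' Classify aligned reads against a junction catalog
#'
#' Emits one event per (read, junction) pair supported by the alignment:
#' \describe{
#'   \item{SPLICED}{an N gap in the CIGAR exactly matches the intron
#'     interval and the flanking aligned blocks have at least
#'     \code{overhang} nt each (exon-exon evidence, \code{b}).}
#'   \item{DONOR / ACCEPTOR}{a contiguous aligned block crosses the intron
#'     5' (3') boundary with at least \code{overhang} aligned nt on each
#'     side and the boundary is measurable (exon-intron evidence,
#'     \code{a}).}
#' }
#' A gap offset by even 1 nt from the annotated intron yields no event, and
#' events at masked boundaries are suppressed. A read may hit several
#' junctions but contributes at most one event per junction (priority
#' SPLICED, then DONOR, then ACCEPTOR, which matters only for a contiguous
#' read spanning a whole short intron). Classification is strand-agnostic:
#' the library protocol strandedness of typical total-RNA data is unknown.
#'
#' @param gal a GAlignments object carrying a \code{mapq} metadata column.
#' @param catalog a [JunctionCatalog-class].
#' @param min_mapq minimum mapping quality (default 10); alignments below
#'   it (or with missing mapq) are ignored.
#' @return a data.frame with columns \code{read} (index into \code{gal}),
#'   \code{qname}, \code{junction} (index into the catalog),
#'   \code{junction_id} and \code{event}.
#' @export
classifyJunctionReads <- function(gal, catalog, min_mapq = 10L) {
    stopifnot(is(catalog, "JunctionCatalog"))
    h <- junctionOverhang(catalog)
    intr <- intronRanges(catalog)
    mq <- mcols(gal)$mapq
    if (is.null(mq))
        stop("alignments must carry a mapq metadata column")
    gal <- gal[!is.na(mq) & mq >= min_mapq]
    empty <- data.frame(read = integer(), qname = character(),
                        junction = integer(), junction_id = character(),
                        event = character())
    if (length(gal) == 0L || length(intr) == 0L)
        return(empty)
    ## drop reads on chromosomes absent from the catalog (logged once each)
    gseq <- as.character(GenomeInfoDb::seqnames(gal))
    known <- gseq %in% seqlevels(intr)
    if (!all(known)) {
        for (chr in unique(gseq[!known]))
            message("ignoring reads on chromosome absent from catalog: ",
                    chr)
        gal <- gal[known]
        if (length(gal) == 0L) return(empty)
    }
    ab <- .alignedBlocks(gal)
    ub <- ab$blocks
    GenomeInfoDb::seqlevels(ub) <- seqlevels(intr)
    rid <- ab$read
    ## ---- spliced evidence: N gaps exactly equal to an intron, anchored
    nb <- length(ub)
    ev <- empty
    if (nb > 1L) {
        adj <- which(rid[-nb] == rid[-1L])
        if (length(adj)) {
            anchored <- width(ub)[adj] >= h & width(ub)[adj + 1L] >= h
            gapr <- GRanges(seqnames(ub)[adj],
                            IRanges(end(ub)[adj] + 1L,
                                    start(ub)[adj + 1L] - 1L))
            hits <- findOverlaps(gapr, intr, type = "equal",
                                 ignore.strand = TRUE)
            q <- S4Vectors::queryHits(hits)
            s <- S4Vectors::subjectHits(hits)
            ok <- anchored[q]
            if (any(ok))
                ev <- rbind(ev, data.frame(
                    read = rid[adj][q[ok]], qname = NA_character_,
                    junction = s[ok], junction_id = NA_character_,
                    event = "SPLICED"))
        }
    }
    ## ---- boundary-crossing evidence: window of h exonic + h intronic
    ## bases must lie within one contiguous aligned block
    .boundaryEvents <- function(windows, which_side) {
        hits <- findOverlaps(windows, ub, type = "within",
                             ignore.strand = TRUE)
        j <- S4Vectors::queryHits(hits)
        r <- rid[S4Vectors::subjectHits(hits)]
        minus <- as.character(strand(intr))[j] == "-"
        event <- if (which_side == "left")
            ifelse(minus, "ACCEPTOR", "DONOR")
        else ifelse(minus, "DONOR", "ACCEPTOR")
        meas <- ifelse(event == "DONOR",
                       intr$donor_measurable[j],
                       intr$acceptor_measurable[j])
        data.frame(read = r, qname = rep(NA_character_, length(r)),
                   junction = j,
                   junction_id = rep(NA_character_, length(r)),
                   event = event)[meas, , drop = FALSE]
    }
    leftw <- GRanges(seqnames(intr),
                     IRanges(start(intr) - h, start(intr) + h - 1L))
    rightw <- GRanges(seqnames(intr),
                      IRanges(end(intr) - h + 1L, end(intr) + h))
    ev <- rbind(ev, .boundaryEvents(leftw, "left"),
                .boundaryEvents(rightw, "right"))
    if (nrow(ev) == 0L) return(empty)
    ## at most one event per (read, junction): SPLICED > DONOR > ACCEPTOR
    prio <- match(ev$event, c("SPLICED", "DONOR", "ACCEPTOR"))
    o <- order(ev$read, ev$junction, prio)
    ev <- ev[o, , drop = FALSE]
    ev <- ev[!duplicated(ev[, c("read", "junction")]), , drop = FALSE]
    ev$qname <- mcols(gal)$qname[ev$read]
    ev$junction_id <- intr$junction_id[ev$junction]
    rownames(ev) <- NULL
    ev
}

#' Count junction reads per sample
#'
#' Streams one or more SAM/BAM files (text SAM is converted on the fly),
#' classifies every primary alignment with [classifyJunctionReads()] and
#' tallies per-junction DONOR/ACCEPTOR/SPLICED events. The per-sample total
#' primary mapped read count (the RPKM denominator) is recorded, and when
#' \code{models} is supplied, per-gene mature read counts and RPKM are
#' computed as well: a read is mature evidence for a gene when its aligned
#' blocks overlap the gene's exons and none of the gene's annotated introns
#' (reads whose splice gaps match the gene's junctions therefore count).
#'
#' @param files character vector of SAM/BAM paths; names are used as sample
#'   identifiers (default: file base name).
#' @param catalog a [JunctionCatalog-class].
#' @param models optional [GeneModels-class]; enables RPKM computation.
#' @param min_mapq minimum mapping quality for classification (default 10).
#' @return a [JunctionCountSet-class].
#' @export
countJunctions <- function(files, catalog, models = NULL, min_mapq = 10L) {
    stopifnot(is(catalog, "JunctionCatalog"), length(files) >= 1L)
    samples <- names(files)
    if (is.null(samples))
        samples <- sub("\\.(sam|bam)$", "", basename(files),
                       ignore.case = TRUE)
    if (anyDuplicated(samples))
        stop("duplicate sample identifiers: ",
             paste(samples[duplicated(samples)], collapse = ", "))
    intr <- intronRanges(catalog)
    countsL <- vector("list", length(files))
    geneL <- vector("list", length(files))
    tm <- setNames(numeric(length(files)), samples)
    for (i in seq_along(files)) {
        gal <- .readPrimary(files[[i]])
        tm[i] <- length(gal)
        ev <- classifyJunctionReads(gal, catalog, min_mapq = min_mapq)
        jf <- factor(ev$junction, levels = seq_along(intr))
        ef <- factor(ev$event, levels = c("DONOR", "ACCEPTOR", "SPLICED"))
        tab <- table(jf, ef)
        countsL[[i]] <- DataFrame(
            junction_id = intr$junction_id,
            sample_id = samples[i],
            a_donor = as.integer(tab[, "DONOR"]),
            a_acceptor = as.integer(tab[, "ACCEPTOR"]),
            b = as.integer(tab[, "SPLICED"]))
        if (!is.null(models)) {
            mat <- matureReadCounts(gal, models, catalog,
                                    min_mapq = min_mapq)
            ## RPKM is undefined without mapped reads (empty alignment
            ## file); keep the zero counts and report NA
            rpkm <- if (tm[i] > 0) computeRpkm(mat, models, tm[i])
                    else rep(NA_real_, length(mat))
            geneL[[i]] <- DataFrame(
                gene_id = names(mat), sample_id = samples[i],
                mature_count = as.integer(mat),
                rpkm = unname(rpkm))
        }
    }
    gc <- if (is.null(models)) DataFrame(gene_id = character(),
                                         sample_id = character(),
                                         mature_count = integer(),
                                         rpkm = numeric())
          else do.call(rbind, geneL)
    new("JunctionCountSet", counts = do.call(rbind, countsL),
        geneCounts = gc, totalMapped = tm, samples = samples)
}

#' Per-gene mature read counts
#'
#' Counts, for every gene, the primary alignments whose aligned blocks
#' overlap the gene's (union) exons while overlapping none of the gene's
#' annotated introns. Spliced reads whose N gaps coincide with the gene's
#' junctions have intron-free blocks and are therefore included.
#'
#' @inheritParams classifyJunctionReads
#' @param models a [GeneModels-class].
#' @return named integer vector over all genes of \code{models}.
#' @export
matureReadCounts <- function(gal, models, catalog, min_mapq = 10L) {
    stopifnot(is(models, "GeneModels"), is(catalog, "JunctionCatalog"))
    gid <- geneIds(models)
    out <- setNames(integer(length(gid)), gid)
    mq <- mcols(gal)$mapq
    gal <- gal[!is.na(mq) & mq >= min_mapq]
    if (length(gal) == 0L) return(out)
    ex <- exonRanges(models)
    exu <- unlist(reduce(S4Vectors::split(
        GRanges(seqnames(ex), IRanges(start(ex), end(ex))),
        factor(ex$gene_id, levels = gid))))
    exGene <- match(names(exu), gid)
    intr <- intronRanges(catalog)
    inGene <- match(intr$gene_id, gid)
    ab <- .alignedBlocks(gal)
    ub <- ab$blocks
    rid <- ab$read
    k <- length(gid) + 1
    hitsE <- findOverlaps(ub, exu, ignore.strand = TRUE)
    keyE <- unique(rid[S4Vectors::queryHits(hitsE)] * k +
                   exGene[S4Vectors::subjectHits(hitsE)])
    hitsI <- findOverlaps(ub, intr, ignore.strand = TRUE)
    keyI <- unique(rid[S4Vectors::queryHits(hitsI)] * k +
                   inGene[S4Vectors::subjectHits(hitsI)])
    keep <- keyE[!(keyE %in% keyI)]
    tab <- table(factor(keep %% k, levels = seq_along(gid)))
    out[] <- as.integer(tab)
    out
}

#' Compute RPKM from mature read counts
#'
#' RPKM_g = mature_count_g / (merged_exon_length_g / 1000) /
#' (total_mapped / 1e6); the gene length is the union of its annotated exon
#' intervals.
#'
#' @param counts named numeric vector of per-gene mature read counts.
#' @param models a [GeneModels-class] supplying merged exon lengths.
#' @param total_mapped total primary mapped read count (> 0).
#' @return named numeric vector of RPKM values.
#' @export
computeRpkm <- function(counts, models, total_mapped) {
    stopifnot(is(models, "GeneModels"))
    if (length(total_mapped) != 1L || is.na(total_mapped) ||
        total_mapped <= 0)
        stop("total_mapped must be a single count > 0")
    len <- mergedExonLength(models)
    if (is.null(names(counts)))
        stop("counts must be named by gene_id")
    miss <- setdiff(names(counts), names(len))
    if (length(miss))
        stop("genes absent from models: ", paste(miss, collapse = ", "))
    len <- len[names(counts)]
    as.numeric(counts) / (len / 1e3) / (total_mapped / 1e6)
}
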