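#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- isTRUEorFALSE
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#'   findOverlaps reduce
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb seqlevels seqnames<-
NULL

#' Gene models parsed from a GTF annotation
#'
#' Container for the exon structure of a set of genes. The \code{exons} slot
#' holds one range per annotated exon record (1-based closed GRanges, the
#' native Bioconductor convention) with \code{gene_id} and
#' \code{transcript_id} metadata columns; the \code{genes} slot summarises one
#' row per gene with its chromosome, strand and merged (union) exon length in
#' nucleotides, which is the kilobase denominator used for RPKM.
#'
#' @slot exons GRanges of exon records with gene_id/transcript_id mcols.
#' @slot genes DataFrame with columns gene_id, chrom, strand,
#'   merged_exon_length; one row per gene, rownames = gene_id.
#'
#' @seealso [readGeneModels()], [buildJunctionCatalog()]
#' @export
setClass("GeneModels", slots = c(exons = "GRanges", genes = "DataFrame"))

setValidity("GeneModels", function(object) {
    msg <- character()
    req <- c("gene_id", "transcript_id")
    if (!all(req %in% colnames(mcols(object@exons))))
        msg <- c(msg, "exons must carry gene_id and transcript_id mcols")
    if (length(object@exons) && any(width(object@exons) < 1L))
        msg <- c(msg, "every exon must have start <= end (width >= 1)")
    reqg <- c("gene_id", "chrom", "strand", "merged_exon_length")
    if (!all(reqg %in% colnames(object@genes)))
        msg <- c(msg, "genes must have gene_id, chrom, strand, merged_exon_length")
    if (length(msg)) msg else TRUE
})

#' Catalog of annotated intron junctions
#'
#' One record per distinct (gene, intron interval) over all transcripts. Each
#' intron is stored as a 1-based closed genomic range covering the intronic
#' bases; the exon-exon junction it measures is the splice joining the bases
#' immediately flanking the range. Metadata columns carry the junction
#' identifier, the owning gene, per-boundary measurability flags (a boundary
#' is non-measurable when its first \code{overhang} intronic bases are exonic
#' in any overlapping annotated transcript, so reads there cannot be
#' unambiguous retention evidence) and an \code{ambiguous} flag for junctions
#' whose coordinates are shared by more than one gene.
#'
#' @slot introns GRanges with mcols junction_id, gene_id, donor_measurable,
#'   acceptor_measurable, ambiguous.
#' @slot overhang integer; minimum aligned anchor (nt) on each side of a
#'   boundary or splice gap for a read to count as junction evidence.
#'
#' @seealso [buildJunctionCatalog()], [countJunctions()]
#' @export
setClass("JunctionCatalog",
         slots = c(introns = "GRanges", overhang = "integer"))

setValidity("JunctionCatalog", function(object) {
    msg <- character()
    req <- c("junction_id", "gene_id", "donor_measurable",
             "acceptor_measurable", "ambiguous")
    if (!all(req %in% colnames(mcols(object@introns))))
        msg <- c(msg, paste("introns must carry mcols:",
                            paste(req, collapse = ", ")))
    if (length(object@introns) && any(width(object@introns) < 1L))
        msg <- c(msg, "every intron must satisfy intron_start < intron_end")
    if (length(object@overhang) != 1L || is.na(object@overhang) ||
        object@overhang < 1L)
        msg <- c(msg, "overhang must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' Per-sample junction read counts
#'
#' Result container of [countJunctions()]. \code{counts} has one row per
#' junction x sample with the exon-intron boundary tallies (\code{a_donor},
#' \code{a_acceptor}) and the exon-exon splice tally (\code{b});
#' \code{geneCounts} has per-gene mature (intron-free) read counts and RPKM;
#' \code{totalMapped} is the per-sample primary mapped read count used as the
#' RPKM denominator.
#'
#' @slot counts DataFrame(junction_id, sample_id, a_donor, a_acceptor, b).
#' @slot geneCounts DataFrame(gene_id, sample_id, mature_count, rpkm).
#' @slot totalMapped named numeric, one entry per sample.
#' @slot samples character vector of sample identifiers.
#' @export
setClass("JunctionCountSet",
         slots = c(counts = "DataFrame", geneCounts = "DataFrame",
                   totalMapped = "numeric", samples = "character"))

setValidity("JunctionCountSet", function(object) {
    msg <- character()
    req <- c("junction_id", "sample_id", "a_donor", "a_acceptor", "b")
    if (!all(req %in% colnames(object@counts)))
        msg <- c(msg, paste("counts must have columns:",
                            paste(req, collapse = ", ")))
    cnt <- as.data.frame(object@counts)[, c("a_donor", "a_acceptor", "b")]
    if (nrow(cnt) && (any(unlist(cnt) < 0) || any(unlist(cnt) %% 1 != 0)))
        msg <- c(msg, "all counts must be nonnegative integers")
    if (!all(object@samples %in% names(object@totalMapped)))
        msg <- c(msg, "totalMapped must be named by sample")
    if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------------
## Generics

#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))
#' @export
setGeneric("exonRanges", function(x, ...) standardGeneric("exonRanges"))
#' @export
setGeneric("mergedExonLength",
           function(x, ...) standardGeneric("mergedExonLength"))
#' @export
setGeneric("intronRanges", function(x, ...) standardGeneric("intronRanges"))
#' @export
setGeneric("junctionOverhang",
           function(x, ...) standardGeneric("junctionOverhang"))
#' @export
setGeneric("countsTable", function(x, ...) standardGeneric("countsTable"))
#' @export
setGeneric("geneCountsTable",
           function(x, ...) standardGeneric("geneCountsTable"))
#' @export
setGeneric("totalMapped", function(x, ...) standardGeneric("totalMapped"))
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

## ------------------------------------------------------------------------
## Accessors

#' @describeIn GeneModels-class gene identifiers
#' @param x a GeneModels, JunctionCatalog or JunctionCountSet object
#' @param ... unused
#' @export
setMethod("geneIds", "GeneModels", function(x, ...) x@genes$gene_id)

#' @describeIn GeneModels-class exon records as a GRanges with
#'   gene_id/transcript_id mcols; optionally restricted to one gene
#' @param gene optional gene identifier to subset to
#' @export
setMethod("exonRanges", "GeneModels", function(x, gene = NULL, ...) {
    if (is.null(gene)) x@exons else x@exons[x@exons$gene_id %in% gene]
})

#' @describeIn GeneModels-class named integer vector of union-exon lengths
#' @export
setMethod("mergedExonLength", "GeneModels", function(x, ...) {
    setNames(as.integer(x@genes$merged_exon_length), x@genes$gene_id)
})

#' @describeIn GeneModels-class number of genes
#' @export
setMethod("length", "GeneModels", function(x) nrow(x@genes))

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels with", nrow(object@genes), "genes,",
        length(unique(paste(object@exons$gene_id,
                            object@exons$transcript_id))),
        "transcripts,", length(object@exons), "exon records\n")
})

#' @describeIn JunctionCatalog-class intron ranges (GRanges, 1-based closed)
#' @param x a JunctionCatalog
#' @param ... unused
#' @export
setMethod("intronRanges", "JunctionCatalog", function(x, ...) x@introns)

#' @describeIn JunctionCatalog-class anchoring overhang in nt
#' @export
setMethod("junctionOverhang", "JunctionCatalog", function(x, ...) x@overhang)

#' @describeIn JunctionCatalog-class gene identifiers (one per junction)
#' @export
setMethod("geneIds", "JunctionCatalog", function(x, ...) x@introns$gene_id)

#' @describeIn JunctionCatalog-class number of junctions
#' @export
setMethod("length", "JunctionCatalog", function(x) length(x@introns))

setMethod("show", "JunctionCatalog", function(object) {
    ir <- object@introns
    cat("JunctionCatalog with", length(ir), "junctions in",
        length(unique(ir$gene_id)), "genes (overhang",
        object@overhang, "nt)\n")
    if (length(ir))
        cat("  measurable boundaries:", sum(ir$donor_measurable), "donor /",
            sum(ir$acceptor_measurable), "acceptor;",
            sum(ir$ambiguous), "ambiguous\n")
})

#' @describeIn JunctionCountSet-class junction-level counts
#' @param x a JunctionCountSet
#' @param ... unused
#' @export
setMethod("countsTable", "JunctionCountSet", function(x, ...) x@counts)

#' @describeIn JunctionCountSet-class per-gene mature counts and RPKM
#' @export
setMethod("geneCountsTable", "JunctionCountSet", function(x, ...) x@geneCounts)

#' @describeIn JunctionCountSet-class per-sample primary mapped read totals
#' @export
setMethod("totalMapped", "JunctionCountSet", function(x, ...) x@totalMapped)

#' @describeIn JunctionCountSet-class sample identifiers
#' @export
setMethod("sampleIds", "JunctionCountSet", function(x, ...) x@samples)

setMethod("show", "JunctionCountSet", function(object) {
    cat("JunctionCountSet:", nrow(object@counts), "junction x sample rows,",
        length(object@samples), "sample(s)\n")
    tm <- object@totalMapped
    cat("  total primary mapped:",
        paste(names(tm), tm, sep = "=", collapse = ", "), "\n")
})
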