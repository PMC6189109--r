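test_that("GTF coordinates and merged exon length follow the exon union", {
    ## single exon [100, 200] 1-based inclusive -> width 101
    gtf <- writeToyGtf(tempfile(fileext = ".gtf"),
                       data.frame(chrom = "chr1", start = 100, end = 200,
                                  strand = "+", gene = "g1", tx = "g1.t1"))
    gm <- readGeneModels(gtf)
    ex <- exonRanges(gm)
    expect_equal(GenomicRanges::start(ex), 100)
    expect_equal(GenomicRanges::end(ex), 200)
    expect_equal(unname(mergedExonLength(gm)), 101L)

    ## disjoint exons of lengths 100 / 50 / 150 -> 300
    gtf3 <- writeToyGtf(tempfile(fileext = ".gtf"),
                        data.frame(chrom = "chr1",
                                   start = c(1, 201, 401),
                                   end = c(100, 250, 550),
                                   strand = "+", gene = "g1",
                                   tx = "g1.t1"))
    expect_equal(unname(mergedExonLength(readGeneModels(gtf3))), 300L)

    ## random gene sets: merged length equals a base-by-base union count;
    ## t1 exons are disjoint, t2 adds an overlapping exon so the union
    ## is smaller than the summed lengths
    set.seed(11)
    for (rep in 1:10) {
        k <- sample(2:5, 1)
        s <- integer(k); e <- integer(k)
        pos <- 1L
        for (j in seq_len(k)) {
            s[j] <- pos
            e[j] <- pos + sample(10:80, 1)
            pos <- e[j] + sample(5:40, 1)
        }
        s2 <- s[1] + 3L
        e2 <- e[1] + sample(10:30, 1)
        rows <- rbind(
            data.frame(chrom = "chrZ", start = s, end = e,
                       strand = "+", gene = "gR", tx = "gR.t1"),
            data.frame(chrom = "chrZ", start = s2, end = e2,
                       strand = "+", gene = "gR", tx = "gR.t2"))
        gm <- readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"), rows))
        expect_equal(unname(mergedExonLength(gm)),
                     bfUnionLength(c(s, s2), c(e, e2)))
    }
})

test_that("transcript grouping and parse errors", {
    exons <- data.frame(chrom = "chr1",
                        start = c(1, 201, 1, 201),
                        end = c(100, 300, 100, 300),
                        strand = "+", gene = "g1",
                        tx = rep(c("g1.t1", "g1.t2"), each = 2))
    gm <- readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"), exons))
    expect_equal(length(gm), 1L)
    expect_setequal(unique(exonRanges(gm)$transcript_id),
                    c("g1.t1", "g1.t2"))

    ## malformed line reported by number
    bad <- tempfile(fileext = ".gtf")
    writeLines(c(paste("chr1", "t", "exon", "1", "100", ".", "+", ".",
                       'gene_id "g"; transcript_id "t";', sep = "\t"),
                 "chr1\tbroken"), bad)
    expect_error(readGeneModels(bad), "line 2")

    ## exon without transcript_id
    noTx <- tempfile(fileext = ".gtf")
    writeLines(paste("chr1", "t", "exon", "1", "100", ".", "+", ".",
                     'gene_id "g";', sep = "\t"), noTx)
    expect_error(readGeneModels(noTx), "transcript_id")
})

test_that("junction catalog equals brute-force gap enumeration", {
    ## one 2-exon transcript -> exactly one junction, both ends measurable
    toy <- toyOneJunction(1001L, 1200L)
    expect_equal(length(toy$catalog), 1L)
    intr <- intronRanges(toy$catalog)
    expect_equal(GenomicRanges::start(intr), 1001L)
    expect_equal(GenomicRanges::end(intr), 1200L)
    expect_true(intr$donor_measurable && intr$acceptor_measurable)

    ## identical intron chains in two transcripts are deduplicated
    exons <- data.frame(chrom = "chr1",
                        start = c(1, 201, 1, 201),
                        end = c(100, 300, 100, 300),
                        strand = "+", gene = "g1",
                        tx = rep(c("g1.t1", "g1.t2"), each = 2))
    cat2 <- buildJunctionCatalog(
        readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"), exons)))
    expect_equal(length(cat2), 1L)

    ## random toy annotations: per-gene junction set equals the union of
    ## per-transcript consecutive-exon gaps, enumerated by brute force
    set.seed(21)
    for (rep in 1:15) {
        case <- randomToyCase()
        ex <- exonRanges(case$models)
        expected <- unique(do.call(rbind, lapply(
            split(as.data.frame(ex),
                  paste(ex$gene_id, ex$transcript_id)),
            function(df) {
                df <- df[order(df$start), ]
                if (nrow(df) < 2) return(NULL)
                data.frame(gene = df$gene_id[1],
                           s = df$end[-nrow(df)] + 1L,
                           e = df$start[-1] - 1L)
            })))
        got <- intronRanges(case$catalog)
        gotKey <- sort(paste(got$gene_id, GenomicRanges::start(got),
                             GenomicRanges::end(got)))
        expKey <- sort(paste(expected$gene, expected$s, expected$e))
        expect_equal(gotKey, expKey)
    }
})

test_that("junctions shared between genes are flagged ambiguous", {
    exons <- data.frame(chrom = "chr1",
                        start = c(1, 201, 1, 201),
                        end = c(100, 300, 100, 300),
                        strand = "+", gene = rep(c("g1", "g2"), each = 2),
                        tx = rep(c("g1.t1", "g2.t1"), each = 2))
    cat2 <- buildJunctionCatalog(
        readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"), exons)))
    expect_equal(length(cat2), 2L)  # kept separately per gene
    expect_true(all(intronRanges(cat2)$ambiguous))
})

test_that("boundary masking by overlapping exons", {
    ## gene gA: exons [801,1000] and [1201,1400], intron [1001,1200];
    ## alt transcript exon covers the first 10 intronic bases
    exons <- data.frame(chrom = "chr1",
                        start = c(801, 1201, 801, 1201),
                        end = c(1000, 1400, 1010, 1400),
                        strand = "+", gene = "gA",
                        tx = rep(c("gA.t1", "gA.t2"), each = 2))
    cat6 <- buildJunctionCatalog(
        readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"), exons)),
        overhang = 6L)
    intr <- intronRanges(cat6)
    j <- intr[GenomicRanges::start(intr) == 1001L]
    expect_false(j$donor_measurable)   # + strand: donor = left boundary
    expect_true(j$acceptor_measurable)

    ## same geometry on the minus strand masks the acceptor instead
    exons$strand <- "-"
    catm <- buildJunctionCatalog(
        readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"), exons)),
        overhang = 6L)
    intr <- intronRanges(catm)
    j <- intr[GenomicRanges::start(intr) == 1001L]
    expect_true(j$donor_measurable)
    expect_false(j$acceptor_measurable)

    ## an overhang smaller than the exonic overrun is still masked,
    ## one larger than the intron is clipped but stays masked
    cat10 <- buildJunctionCatalog(
        readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"), exons)),
        overhang = 12L)
    j <- intronRanges(cat10)[GenomicRanges::start(intronRanges(cat10)) ==
                             1001L]
    expect_false(j$acceptor_measurable)
})

test_that("catalog TSV round trip preserves coordinates and flags", {
    set.seed(31)
    case <- randomToyCase()
    path <- tempfile(fileext = ".tsv")
    writeJunctionCatalog(case$catalog, path)
    ## exported coordinates are 0-based half-open
    df <- utils::read.delim(path, comment.char = "#")
    intr <- intronRanges(case$catalog)
    expect_equal(df$intron_start, GenomicRanges::start(intr) - 1L)
    expect_equal(df$intron_end, GenomicRanges::end(intr))
    back <- readJunctionCatalog(path)
    expect_equal(junctionOverhang(back), junctionOverhang(case$catalog))
    expect_equal(as.data.frame(intronRanges(back)),
                 as.data.frame(intr))

    ## empty gene list -> empty catalog, not an error
    empty <- buildJunctionCatalog(
        readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"),
            data.frame(chrom = "chr1", start = 1, end = 100,
                       strand = "+", gene = "g1", tx = "g1.t1"))))
    expect_equal(length(empty), 0L)
})
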