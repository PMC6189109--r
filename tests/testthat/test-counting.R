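## One junction: intron [1001, 1200] flanked by 200-nt exons on chrT.

test_that("reads are classified by boundary spanning and exact gaps", {
    toy <- toyOneJunction(1001L, 1200L)
    reads <- data.frame(
        qname = c("donor", "spliced", "offgap", "lowq", "shortanchor",
                  "acceptor"),
        pos = c(981,          # 40M crossing 1000|1001 with 20 nt each side
                971,          # 30M 200N 30M: gap exactly [1001,1200]
                972,          # same shape shifted by 1 -> no event
                981,          # donor geometry but mapq below cutoff
                996,          # 10M: 5 exonic + 5 intronic < overhang
                1181),        # 40M crossing 1200|1201
        cigar = c("40M", "30M200N30M", "30M200N30M", "40M", "10M", "40M"),
        mapq = c(60, 60, 60, 5, 60, 60))
    sam <- writeToySam(tempfile(fileext = ".sam"), reads)
    ev <- classifyJunctionReads(readToySam(sam), toy$catalog)
    got <- setNames(ev$event, ev$qname)
    expect_equal(got[["donor"]], "DONOR")
    expect_equal(got[["spliced"]], "SPLICED")
    expect_equal(got[["acceptor"]], "ACCEPTOR")
    expect_false(any(c("offgap", "lowq", "shortanchor") %in% ev$qname))
})

test_that("hand-built SAM tallies donor/acceptor/spliced counts", {
    toy <- toyOneJunction(1001L, 1200L)
    reads <- rbind(
        data.frame(qname = paste0("d", 1:5), pos = 981 + 0:4,
                   cigar = "40M", mapq = 60),
        data.frame(qname = paste0("a", 1:3), pos = 1181 + 0:2,
                   cigar = "40M", mapq = 60),
        data.frame(qname = paste0("s", 1:12), pos = 971 - 0:11,
                   cigar = paste0(30 + 0:11, "M200N30M"), mapq = 60))
    sam <- writeToySam(tempfile(fileext = ".sam"), reads)
    cs <- countJunctions(c(s1 = sam), toy$catalog)
    cnt <- as.data.frame(countsTable(cs))
    expect_equal(cnt$a_donor, 5L)
    expect_equal(cnt$a_acceptor, 3L)
    expect_equal(cnt$b, 12L)
    expect_equal(unname(totalMapped(cs)), 20)

    ## empty SAM -> all-zero counts
    empty <- writeToySam(tempfile(fileext = ".sam"),
                         data.frame(qname = character(), pos = integer(),
                                    cigar = character(), mapq = integer()))
    cs0 <- countJunctions(c(s1 = empty), toy$catalog)
    cnt0 <- as.data.frame(countsTable(cs0))
    expect_equal(cnt0$a_donor + cnt0$a_acceptor + cnt0$b, 0L)
})

test_that("masked boundaries never accumulate counts", {
    ## alt transcript exon covers the first 10 intronic bases -> the
    ## + strand donor of intron [1001,1200] is unmeasurable
    exons <- data.frame(chrom = "chrT",
                        start = c(801, 1201, 801, 1201),
                        end = c(1000, 1400, 1010, 1400),
                        strand = "+", gene = "gA",
                        tx = rep(c("gA.t1", "gA.t2"), each = 2))
    models <- readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"),
                                         exons))
    catalog <- buildJunctionCatalog(models, overhang = 6L)
    reads <- data.frame(qname = paste0("d", 1:8), pos = 981 + 0:7,
                        cigar = "40M", mapq = 60)
    sam <- writeToySam(tempfile(fileext = ".sam"), reads)
    cs <- countJunctions(c(s1 = sam), catalog)
    cnt <- as.data.frame(countsTable(cs))
    j1 <- cnt[grepl(":1000-1200$", cnt$junction_id), ]
    expect_equal(j1$a_donor, 0L)
})

test_that("counts are invariant to read order and multi-junction reads
           contribute once per junction", {
    set.seed(41)
    case <- randomToyCase()
    reads <- randomToyReads(case, n = 60L)
    sam1 <- writeToySam(tempfile(fileext = ".sam"), reads,
                        chromLen = case$maxpos + 1000L)
    shuffled <- reads[sample(nrow(reads)), ]
    sam2 <- writeToySam(tempfile(fileext = ".sam"), shuffled,
                        chromLen = case$maxpos + 1000L)
    c1 <- as.data.frame(countsTable(countJunctions(c(s = sam1),
                                                   case$catalog)))
    c2 <- as.data.frame(countsTable(countJunctions(c(s = sam2),
                                                   case$catalog)))
    expect_identical(c1, c2)

    ## at most one event per (read, junction): a contiguous read spanning
    ## a whole intron crosses both boundaries but is counted once
    toy <- toyOneJunction(1001L, 1050L)
    sam <- writeToySam(tempfile(fileext = ".sam"),
                       data.frame(qname = "span", pos = 991,
                                  cigar = "70M", mapq = 60))
    ev <- classifyJunctionReads(readToySam(sam), toy$catalog)
    expect_equal(nrow(ev), 1L)
})

test_that("reads on chromosomes absent from the catalog are ignored", {
    toy <- toyOneJunction(1001L, 1200L)
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 "@SQ\tSN:chrT\tLN:100000",
                 "@SQ\tSN:chrUn\tLN:100000",
                 paste("r1", 0, "chrUn", 981, 60, "40M", "*", 0, 0, "*",
                       "*", sep = "\t"),
                 paste("r2", 0, "chrT", 981, 60, "40M", "*", 0, 0, "*",
                       "*", sep = "\t")), sam)
    expect_message(
        ev <- classifyJunctionReads(readToySam(sam), toy$catalog),
        "chrUn")
    expect_equal(ev$qname, "r2")
})

test_that("RPKM follows the unit definition and a brute-force overlap
           oracle", {
    toy <- toyOneJunction(1001L, 1200L)  # merged exon length 400
    gm1k <- readGeneModels(writeToyGtf(tempfile(fileext = ".gtf"),
        data.frame(chrom = "chrT", start = 1, end = 1000, strand = "+",
                   gene = "gk", tx = "gk.t1")))
    expect_equal(unname(computeRpkm(c(gk = 1000), gm1k, 1e6)), 1000)
    expect_equal(unname(computeRpkm(c(gk = 2000), gm1k, 1e6)), 2000)
    expect_error(computeRpkm(c(gk = 10), gm1k, 0), "total_mapped")

    ## three-gene toy dataset: mature counts equal a per-read loop oracle
    set.seed(51)
    case <- randomToyCase()
    reads <- randomToyReads(case, n = 80L)
    sam <- writeToySam(tempfile(fileext = ".sam"), reads,
                       chromLen = case$maxpos + 1000L)
    gal <- readToySam(sam)
    got <- matureReadCounts(gal, case$models, case$catalog)
    ex <- as.data.frame(exonRanges(case$models))
    intr <- intronRanges(case$catalog)
    indf <- data.frame(gene = intr$gene_id,
                       s = GenomicRanges::start(intr),
                       e = GenomicRanges::end(intr))
    keep <- reads$mapq >= 10
    expected <- setNames(integer(length(geneIds(case$models))),
                         geneIds(case$models))
    for (i in which(keep)) {
        blocks <- bfBlocks(reads$pos[i], reads$cigar[i])
        for (g in names(expected)) {
            exg <- ex[ex$gene_id == g, ]
            ing <- indf[indf$gene == g, ]
            hitE <- any(vapply(blocks, function(b)
                any(b[1] <= exg$end & b[2] >= exg$start), NA))
            hitI <- nrow(ing) > 0 && any(vapply(blocks, function(b)
                any(b[1] <= ing$e & b[2] >= ing$s), NA))
            if (hitE && !hitI) expected[g] <- expected[g] + 1L
        }
    }
    expect_equal(got, expected)
})
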