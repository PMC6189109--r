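## Brute-force oracles and toy-data writers, implemented independently of
## the package internals (plain loops over bases/positions).

## CIGAR -> list of reference-contiguous blocks c(start, end), 1-based.
bfBlocks <- function(pos, cigar) {
    toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1L]]
    len <- as.integer(sub(".$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    blocks <- list()
    cur_s <- pos
    cur_e <- pos - 1L
    for (i in seq_along(op)) {
        if (op[i] %in% c("M", "D", "=", "X")) {
            cur_e <- cur_e + len[i]
        } else if (op[i] == "N") {
            blocks[[length(blocks) + 1L]] <- c(cur_s, cur_e)
            cur_s <- cur_e + len[i] + 1L
            cur_e <- cur_s - 1L
        }
        ## I, S, H, P consume no reference
    }
    blocks[[length(blocks) + 1L]] <- c(cur_s, cur_e)
    blocks
}

## Direct per-read-per-junction test of the classification contract.
## junction: list(start, end, strand, donor_meas, acc_meas) 1-based closed.
bfClassifyOne <- function(pos, cigar, mapq, junction, h, min_mapq = 10) {
    if (is.na(mapq) || mapq < min_mapq) return(NULL)
    blocks <- bfBlocks(pos, cigar)
    js <- junction$start
    je <- junction$end
    ev <- character()
    for (i in seq_along(blocks)) {
        b <- blocks[[i]]
        if (i < length(blocks)) {
            b2 <- blocks[[i + 1L]]
            if (b[2L] == js - 1L && b2[1L] == je + 1L &&
                (b[2L] - b[1L] + 1L) >= h && (b2[2L] - b2[1L] + 1L) >= h)
                ev <- c(ev, "SPLICED")
        }
        if (b[1L] <= js - h && b[2L] >= js + h - 1L)
            ev <- c(ev, if (junction$strand == "-") "ACCEPTOR" else "DONOR")
        if (b[1L] <= je - h + 1L && b[2L] >= je + h)
            ev <- c(ev, if (junction$strand == "-") "DONOR" else "ACCEPTOR")
    }
    ev <- ev[!(ev == "DONOR" & !junction$donor_meas)]
    ev <- ev[!(ev == "ACCEPTOR" & !junction$acc_meas)]
    for (e in c("SPLICED", "DONOR", "ACCEPTOR"))
        if (e %in% ev) return(e)
    NULL
}

## Brute-force length of the union of closed intervals.
bfUnionLength <- function(starts, ends) {
    length(unique(unlist(Map(seq, starts, ends))))
}

## Brute-force branch-site scan: all placements scored base by base.
bfScanBranch <- function(seq, consensus = "UCCUGNC", branch_pos = 6L,
                         window = 100L, min_score = nchar(consensus)) {
    map <- c(A = "A", C = "C", G = "G", T = "T", M = "AC", R = "AG",
             W = "AT", S = "CG", Y = "CT", K = "GT", V = "ACG",
             H = "ACT", D = "AGT", B = "CGT", N = "ACGT")
    sch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1L]]
    cch <- strsplit(chartr("U", "T", toupper(consensus)), "")[[1L]]
    cl <- length(cch)
    n <- length(sch)
    window <- min(window, n)
    rows <- list()
    for (p in seq_len(n - cl + 1L)) {
        if (p < n - window + 1L) next
        bpos <- p + branch_pos - 1L
        if (bpos > n - 3L) next
        score <- 0L
        for (j in seq_len(cl)) {
            sset <- strsplit(map[[sch[p + j - 1L]]], "")[[1L]]
            cset <- strsplit(map[[cch[j]]], "")[[1L]]
            if (all(sset %in% cset)) score <- score + 1L
        }
        if (score >= min_score) {
            bnt <- chartr("T", "U", sch[bpos])
            rows[[length(rows) + 1L]] <- data.frame(
                offset_from_3ss = n - bpos,
                matched_seq = chartr("T", "U",
                                     paste(sch[p:(p + cl - 1L)],
                                           collapse = "")),
                branch_nt = bnt, score = score,
                noncanonical = bnt != "A")
        }
    }
    if (!length(rows))
        return(data.frame(offset_from_3ss = integer(),
                          matched_seq = character(),
                          branch_nt = character(), score = integer(),
                          noncanonical = logical()))
    out <- do.call(rbind, rows)
    out <- out[order(-out$score, out$offset_from_3ss), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## ---- toy-data writers -------------------------------------------------

## exons: data.frame(chrom, start, end, strand, gene, tx), 1-based closed.
writeToyGtf <- function(path, exons) {
    writeLines(paste(exons$chrom, "toy", "exon", exons$start, exons$end,
                     ".", exons$strand, ".",
                     sprintf('gene_id "%s"; transcript_id "%s";',
                             exons$gene, exons$tx), sep = "\t"),
               path)
    path
}

## reads: data.frame(qname, pos, cigar, mapq[, flag]); SEQ/QUAL omitted.
writeToySam <- function(path, reads, chrom = "chrT", chromLen = 100000L) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:", chrom, "\tLN:", chromLen))
    body <- character()
    if (nrow(reads)) {
        flag <- if ("flag" %in% names(reads)) reads$flag else 0L
        body <- paste(reads$qname, flag, chrom, reads$pos, reads$mapq,
                      reads$cigar, "*", 0L, 0L, "*", "*", sep = "\t")
    }
    writeLines(c(header, body), path)
    path
}

## A two-exon gene catalog on chrT with one junction [istart, iend]
## (1-based closed intronic bases), flanked by 200 nt exons.
toyOneJunction <- function(istart = 1001L, iend = 1200L, strand = "+",
                           overhang = 6L) {
    exons <- data.frame(chrom = "chrT",
                        start = c(istart - 200L, iend + 1L),
                        end = c(istart - 1L, iend + 200L),
                        strand = strand, gene = "gA",
                        tx = "gA.t1")
    gtf <- writeToyGtf(tempfile(fileext = ".gtf"), exons)
    models <- readGeneModels(gtf)
    list(models = models,
         catalog = buildJunctionCatalog(models, overhang = overhang))
}

## Random toy annotation (1-3 genes, 2-4 exons each) plus the flat
## junction list the brute-force classifier needs. Occasionally adds an
## alternative transcript whose exon extends into an intron, so boundary
## masking comes into play.
randomToyCase <- function() {
    nGenes <- sample(1:3, 1L)
    exon_rows <- list()
    cursor <- 200L
    for (g in seq_len(nGenes)) {
        k <- sample(2:4, 1L)
        strand <- sample(c("+", "-"), 1L)
        es <- integer(k); ee <- integer(k)
        pos <- cursor
        for (j in seq_len(k)) {
            elen <- sample(60:120, 1L)
            es[j] <- pos; ee[j] <- pos + elen - 1L
            pos <- ee[j] + 1L + sample(40:100, 1L)
        }
        gid <- paste0("g", g)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
            chrom = "chrT", start = es, end = ee, strand = strand,
            gene = gid, tx = paste0(gid, ".t1"))
        if (stats::runif(1) < 0.5) {
            ## alt transcript: first exon runs into the first intron
            ext <- sample(3:12, 1L)
            exon_rows[[length(exon_rows) + 1L]] <- data.frame(
                chrom = "chrT",
                start = c(es[1L], es[2L]),
                end = c(ee[1L] + ext, ee[2L]),
                strand = strand, gene = gid, tx = paste0(gid, ".t2"))
        }
        cursor <- ee[k] + 300L
    }
    exons <- do.call(rbind, exon_rows)
    gtf <- writeToyGtf(tempfile(fileext = ".gtf"), exons)
    models <- readGeneModels(gtf)
    catalog <- buildJunctionCatalog(models, overhang = 6L)
    intr <- intronRanges(catalog)
    junctions <- lapply(seq_along(intr), function(i)
        list(start = GenomicRanges::start(intr)[i],
             end = GenomicRanges::end(intr)[i],
             strand = as.character(GenomicRanges::strand(intr))[i],
             donor_meas = intr$donor_measurable[i],
             acc_meas = intr$acceptor_measurable[i],
             id = intr$junction_id[i]))
    list(models = models, catalog = catalog, junctions = junctions,
         maxpos = max(exons$end) + 200L)
}

## Random reads around the junctions of a toy case: boundary-spanning,
## exact-gap, near-miss gaps, and scattered contiguous reads.
randomToyReads <- function(case, n = 40L) {
    rows <- list()
    for (i in seq_len(n)) {
        j <- case$junctions[[sample(length(case$junctions), 1L)]]
        mapq <- sample(c(0L, 5L, 10L, 30L, 60L), 1L)
        kind <- sample(4L, 1L)
        if (kind == 1L) {          # contiguous near a boundary
            L <- sample(20:60, 1L)
            anchor <- sample(c(j$start, j$end), 1L)
            pos <- anchor - sample(0:L, 1L)
            cigar <- paste0(L, "M")
        } else if (kind == 2L) {   # split read, exact or near-miss gap
            off <- sample(c(0L, 0L, -2L, -1L, 1L, 2L), 1L)
            a <- sample(3:30, 1L); b <- sample(3:30, 1L)
            gap <- j$end - j$start + 1L
            pos <- j$start + off - a
            cigar <- paste0(a, "M", gap, "N", b, "M")
        } else if (kind == 3L) {   # contiguous spanning the whole intron
            w <- j$end - j$start + 1L + 2L * sample(3:10, 1L)
            pos <- j$start - (w - (j$end - j$start + 1L)) %/% 2L
            cigar <- paste0(w, "M")
        } else {                   # random placement
            L <- sample(20:60, 1L)
            pos <- sample(seq_len(case$maxpos), 1L)
            cigar <- paste0(L, "M")
        }
        if (pos < 1L) next
        rows[[length(rows) + 1L]] <- data.frame(
            qname = paste0("r", i), pos = pos, cigar = cigar, mapq = mapq)
    }
    do.call(rbind, rows)
}

## Brute-force event table for a read set against every junction.
bfClassifyAll <- function(reads, case, h = 6L, min_mapq = 10L) {
    rows <- list()
    for (i in seq_len(nrow(reads))) {
        for (j in case$junctions) {
            ev <- bfClassifyOne(reads$pos[i], reads$cigar[i],
                                reads$mapq[i], j, h, min_mapq)
            if (!is.null(ev))
                rows[[length(rows) + 1L]] <- data.frame(
                    qname = reads$qname[i], junction_id = j$id,
                    event = ev)
        }
    }
    if (!length(rows))
        return(data.frame(qname = character(), junction_id = character(),
                          event = character()))
    out <- do.call(rbind, rows)
    out[order(out$qname, out$junction_id, out$event), , drop = FALSE]
}

## Read a GAlignments from a toy SAM via the package reader.
readToySam <- function(path) junctionIR:::.readPrimary(path)
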