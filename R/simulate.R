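#' Configuration for the ground-truth read simulator
#'
#' Builds and validates the parameter set for [simulateDataset()]. The
#' simulated design mirrors a knockdown experiment: two conditions (control
#' and knockdown) with \code{n_replicates} each, per-gene expression
#' \code{lambda} (reads per molecule nt), and a per-gene unspliced fraction
#' theta in \[0, 1): each molecule of a gene retains each of its introns
#' independently with probability theta. In the knockdown condition a
#' fraction \code{shift_fraction} of genes has theta raised by
#' \code{theta_shift}, emulating a global splicing impairment; the default
#' shifted fraction of 0.8 mirrors the widespread-retention phenotype in
#' which roughly four fifths of expressed genes gain intron retention after
#' depletion of a splicing factor.
#'
#' Reads of length \code{read_length} are placed uniformly along each
#' molecule. With equal placement-position counts per junction, the
#' expected gene-level IR is \code{2 theta / (1 - theta)} (two exon-intron
#' boundaries per retained intron versus one exon-exon junction per spliced
#' intron); see [expectedGeneIR()].
#'
#' @param n_genes number of genes (default 500).
#' @param exons_per_gene integer range (lo, hi) of exons per gene.
#' @param exon_length,intron_length nt ranges (lo, hi).
#' @param read_length read length L in nt; must be >= 2*overhang.
#' @param overhang junction anchor in nt the reads are simulated for.
#' @param lambda expression: expected reads per molecule nt per replicate.
#' @param theta_ctrl unspliced fraction in control; scalar or (lo, hi)
#'   range sampled uniformly per gene.
#' @param theta_shift additive theta increase in the knockdown (default
#'   0.1).
#' @param shift_fraction fraction of genes receiving the shift (default
#'   0.8).
#' @param n_replicates replicates per condition (default 2).
#' @param seed required integer seed; all randomness derives from it.
#' @param intergenic_gap nt between consecutive genes.
#' @param branch_motif optional literal motif (RNA or DNA spelling) planted
#'   in every intron, in transcript orientation.
#' @param branch_offset nt between the motif end and the intron 3' end.
#' @return a validated config (list of class \code{ir_sim_config}).
#' @export
simConfig <- function(n_genes = 500L,
                      exons_per_gene = c(2L, 4L),
                      exon_length = c(70L, 150L),
                      intron_length = c(80L, 200L),
                      read_length = 75L,
                      overhang = 6L,
                      lambda = 3,
                      theta_ctrl = c(0.05, 0.2),
                      theta_shift = 0.1,
                      shift_fraction = 0.8,
                      n_replicates = 2L,
                      seed,
                      intergenic_gap = 100L,
                      branch_motif = NULL,
                      branch_offset = 20L) {
    if (missing(seed) || length(seed) != 1L || is.na(seed))
        stop("seed is a required scalar field of the simulation config")
    rng <- function(x) if (length(x) == 1L) c(x, x) else sort(x[1:2])
    exons_per_gene <- rng(as.integer(exons_per_gene))
    exon_length <- rng(as.integer(exon_length))
    intron_length <- rng(as.integer(intron_length))
    theta_ctrl <- rng(as.numeric(theta_ctrl))
    if (n_genes < 1L) stop("n_genes must be >= 1")
    if (exons_per_gene[1L] < 2L)
        stop("genes need at least 2 exons to have a junction")
    if (exon_length[1L] < 1L || intron_length[1L] < 1L)
        stop("lengths must be positive")
    if (read_length < 2L * overhang)
        stop("read_length must be >= 2 * overhang")
    if (theta_ctrl[1L] < 0 || theta_ctrl[2L] >= 1)
        stop("theta must lie in [0, 1)")
    if (theta_shift < 0 || theta_ctrl[2L] + theta_shift >= 1)
        stop("theta_ctrl + theta_shift must stay below 1")
    if (shift_fraction < 0 || shift_fraction > 1)
        stop("shift_fraction must lie in [0, 1]")
    if (lambda <= 0) stop("lambda must be > 0")
    if (n_replicates < 1L) stop("n_replicates must be >= 1")
    ## geometry: every junction must admit the full set of anchored read
    ## placements, which needs flanking exons of at least L - overhang nt
    if (exon_length[1L] < read_length - overhang)
        stop("impossible geometry: minimum exon length ",
             exon_length[1L], " nt is shorter than read_length - overhang (",
             read_length - overhang, " nt)")
    structure(list(n_genes = as.integer(n_genes),
                   exons_per_gene = exons_per_gene,
                   exon_length = exon_length,
                   intron_length = intron_length,
                   read_length = as.integer(read_length),
                   overhang = as.integer(overhang),
                   lambda = lambda,
                   theta_ctrl = theta_ctrl,
                   theta_shift = theta_shift,
                   shift_fraction = shift_fraction,
                   n_replicates = as.integer(n_replicates),
                   seed = as.integer(seed),
                   intergenic_gap = as.integer(intergenic_gap),
                   branch_motif = branch_motif,
                   branch_offset = as.integer(branch_offset)),
              class = "ir_sim_config")
}

#' Expected gene-level IR for an unspliced fraction theta
#'
#' Closed form \code{2 theta / (1 - theta)}: a retained intron exposes two
#' exon-intron boundaries while a spliced intron exposes one exon-exon
#' junction, and under uniform read placement each carries the same number
#' of anchored placement positions per molecule.
#'
#' @param theta unspliced fraction(s) in \[0, 1).
#' @return expected IR coefficient(s).
#' @examples
#' expectedGeneIR(c(0, 1/3, 0.5))  # 0, 1, 2
#' @export
expectedGeneIR <- function(theta) {
    if (any(!is.finite(theta)) || any(theta < 0) || any(theta >= 1))
        stop("theta must lie in [0, 1)")
    2 * theta / (1 - theta)
}

## merge exons plus retained introns into contiguous genomic blocks
.patternBlocks <- function(es, ee, is_, ie, retain) {
    s <- c(es, is_[retain])
    e <- c(ee, ie[retain])
    o <- order(s)
    s <- s[o]; e <- e[o]
    grp <- cumsum(c(TRUE, s[-1L] > e[-length(e)] + 1L))
    list(start = as.integer(unname(tapply(s, grp, min))),
         end = as.integer(unname(tapply(e, grp, max))))
}

## CIGAR strings and genomic POS for reads at molecule positions p
.readsOnBlocks <- function(bs, be, p, L) {
    w <- be - bs + 1L
    cum <- cumsum(w)
    cumBefore <- c(0L, cum[-length(cum)])
    si <- findInterval(p - 1L, cum) + 1L
    ei <- findInterval(p + L - 2L, cum) + 1L
    pos <- bs[si] + (p - 1L - cumBefore[si])
    cigar <- character(length(p))
    one <- si == ei
    cigar[one] <- paste0(L, "M")
    two <- ei == si + 1L
    if (any(two)) {
        m1 <- cum[si[two]] - p[two] + 1L
        gap <- bs[ei[two]] - be[si[two]] - 1L
        m2 <- L - m1
        cigar[two] <- paste0(m1, "M", gap, "N", m2, "M")
    }
    multi <- which(ei > si + 1L)
    for (i in multi) {
        parts <- paste0(cum[si[i]] - p[i] + 1L, "M")
        for (j in (si[i] + 1L):ei[i]) {
            gap <- bs[j] - be[j - 1L] - 1L
            m <- min(cum[j], p[i] + L - 1L) - cum[j - 1L]
            parts <- c(parts, paste0(gap, "N", m, "M"))
        }
        cigar[i] <- paste(parts, collapse = "")
    }
    list(pos = pos, cigar = cigar)
}

#' Simulate a toy genome, annotation and aligned reads with known truth
#'
#' Generates a single-chromosome genome (uniform random A/C/G/T background,
#' optionally with a branch motif planted in every intron), a matching GTF
#' (one transcript per gene), one text SAM per condition x replicate with
#' pre-aligned reads (CIGARs containing only M and N), and a truth table
#' recording each gene's theta and expected IR. Spliced-molecule reads that
#' cross an exon-exon junction are written as split alignments whose N gap
#' equals the intron exactly; unspliced-molecule reads are contiguous.
#' Identical configs (including seed) produce byte-identical outputs.
#'
#' @param config a config from [simConfig()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with paths (\code{fasta}, \code{gtf},
#'   \code{sam} named by sample, \code{truth}, \code{config}) and the truth
#'   data.frame (\code{truth_table}).
#' @export
simulateDataset <- function(config, outdir) {
    stopifnot(inherits(config, "ir_sim_config"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    cfg <- config
    n <- cfg$n_genes
    L <- cfg$read_length
    runifInt <- function(m, r) if (r[1L] == r[2L]) rep(r[1L], m)
                               else sample(r[1L]:r[2L], m, replace = TRUE)
    nex <- runifInt(n, cfg$exons_per_gene)
    strandv <- rep(c("+", "-"), length.out = n)
    theta_c <- if (cfg$theta_ctrl[1L] == cfg$theta_ctrl[2L])
        rep(cfg$theta_ctrl[1L], n)
    else stats::runif(n, cfg$theta_ctrl[1L], cfg$theta_ctrl[2L])
    nshift <- round(cfg$shift_fraction * n)
    shifted <- sort(sample.int(n, nshift))
    theta_k <- theta_c
    theta_k[shifted] <- theta_c[shifted] + cfg$theta_shift
    ## ---- gene coordinates on one chromosome
    genes <- vector("list", n)
    cursor <- cfg$intergenic_gap
    for (g in seq_len(n)) {
        k <- nex[g]
        elen <- runifInt(k, cfg$exon_length)
        ilen <- runifInt(k - 1L, cfg$intron_length)
        es <- integer(k); ee <- integer(k)
        pos <- cursor + 1L
        for (j in seq_len(k)) {
            es[j] <- pos; ee[j] <- pos + elen[j] - 1L
            pos <- ee[j] + 1L
            if (j < k) pos <- pos + ilen[j]
        }
        genes[[g]] <- list(es = es, ee = ee,
                           is_ = ee[-k] + 1L, ie = es[-1L] - 1L)
        cursor <- ee[k] + cfg$intergenic_gap
    }
    glen <- cursor
    genome <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    ## ---- optional branch motif planted in every intron
    if (!is.null(cfg$branch_motif)) {
        motif <- chartr("U", "T", toupper(cfg$branch_motif))
        mlen <- nchar(motif)
        mchars <- strsplit(motif, "", fixed = TRUE)[[1L]]
        rcchars <- rev(chartr("ACGT", "TGCA", mchars))
        for (g in seq_len(n)) {
            gi <- genes[[g]]
            for (j in seq_along(gi$is_)) {
                ilen_j <- gi$ie[j] - gi$is_[j] + 1L
                if (ilen_j < mlen + cfg$branch_offset) next
                if (strandv[g] == "+") {
                    at <- gi$ie[j] - cfg$branch_offset - mlen + 1L
                    genome[at:(at + mlen - 1L)] <- mchars
                } else {
                    at <- gi$is_[j] + cfg$branch_offset
                    genome[at:(at + mlen - 1L)] <- rcchars
                }
            }
        }
    }
    genomeStr <- paste(genome, collapse = "")
    fastaPath <- file.path(outdir, "genome.fa")
    seqset <- Biostrings::DNAStringSet(genomeStr)
    names(seqset) <- "chrS"
    Biostrings::writeXStringSet(seqset, fastaPath)
    ## ---- GTF (1-based inclusive), one transcript per gene
    gtfPath <- file.path(outdir, "annotation.gtf")
    lines <- unlist(lapply(seq_len(n), function(g) {
        gi <- genes[[g]]
        paste("chrS", "sim", "exon", gi$es, gi$ee, ".", strandv[g], ".",
              sprintf('gene_id "g%04d"; transcript_id "g%04d.t1";', g, g),
              sep = "\t")
    }))
    writeLines(c("#!genome-build synthetic", lines), gtfPath)
    gene_ids <- sprintf("g%04d", seq_len(n))
    ## ---- per-gene retention patterns (shared across conditions)
    patterns <- lapply(seq_len(n), function(g) {
        gi <- genes[[g]]
        k <- length(gi$is_)
        if (k > 15L) stop("too many introns per gene for enumeration")
        ret <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
        blocks <- lapply(seq_len(nrow(ret)), function(p)
            .patternBlocks(gi$es, gi$ee, gi$is_, gi$ie, ret[p, ]))
        mol <- vapply(blocks, function(b)
            paste(substring(genomeStr, b$start, b$end), collapse = ""), "")
        list(ret = ret, blocks = blocks, mol = mol,
             len = vapply(blocks, function(b)
                 sum(b$end - b$start + 1L), 0L))
    })
    ## ---- reads
    samples <- as.vector(outer(seq_len(cfg$n_replicates),
                               c("ctrl", "kd"),
                               function(r, cond) paste0(cond, "_rep", r)))
    samPaths <- setNames(file.path(outdir, paste0(samples, ".sam")),
                         samples)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:chrS\tLN:", glen))
    for (smp in samples) {
        cond <- sub("_rep.*", "", smp)
        theta <- if (cond == "ctrl") theta_c else theta_k
        recs <- vector("list", n)
        for (g in seq_len(n)) {
            pat <- patterns[[g]]
            th <- theta[g]
            k <- ncol(pat$ret)
            pr <- apply(pat$ret, 1L, function(r)
                prod(ifelse(r, th, 1 - th)))
            m <- pmax(pat$len - L + 1L, 0L)
            w <- pr * m
            tot <- sum(w)
            if (tot <= 0) next
            N <- stats::rpois(1L, cfg$lambda * tot)
            if (N == 0L) next
            np <- as.vector(stats::rmultinom(1L, N, w))
            rl <- vector("list", length(np))
            for (p in which(np > 0L)) {
                pos <- sample.int(m[p], np[p], replace = TRUE)
                rr <- .readsOnBlocks(pat$blocks[[p]]$start,
                                     pat$blocks[[p]]$end, pos, L)
                rl[[p]] <- data.frame(
                    pos = rr$pos, cigar = rr$cigar,
                    seq = substring(pat$mol[p], pos, pos + L - 1L))
            }
            recs[[g]] <- cbind(gene = gene_ids[g],
                               do.call(rbind, rl[lengths(rl) > 0L]))
        }
        recs <- do.call(rbind, recs[lengths(recs) > 0L])
        con <- file(samPaths[smp], "w")
        writeLines(header, con)
        if (!is.null(recs) && nrow(recs)) {
            qname <- paste0(smp, ":", recs$gene, ":",
                            seq_len(nrow(recs)))
            writeLines(paste(qname, 0L, "chrS", recs$pos, 60L,
                             recs$cigar, "*", 0L, 0L, recs$seq, "*",
                             sep = "\t"), con)
        }
        close(con)
    }
    ## ---- truth table
    truth <- data.frame(gene_id = gene_ids,
                        strand = strandv,
                        n_introns = nex - 1L,
                        lambda = cfg$lambda,
                        theta_ctrl = theta_c,
                        theta_kd = theta_k,
                        expected_ir_ctrl = expectedGeneIR(theta_c),
                        expected_ir_kd = expectedGeneIR(theta_k))
    truth$expected_fold <- ifelse(truth$expected_ir_ctrl > 0,
                                  truth$expected_ir_kd /
                                      truth$expected_ir_ctrl, NA_real_)
    truth$aberrant_truth <- !is.na(truth$expected_fold) &
        truth$expected_fold > 1.15
    truthPath <- file.path(outdir, "truth.tsv")
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cfgPath <- file.path(outdir, "sim_config.json")
    cfgOut <- config
    cfgOut$branch_motif <- if (is.null(cfgOut$branch_motif)) NA_character_
                           else cfgOut$branch_motif
    jsonlite::write_json(unclass(cfgOut), cfgPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(fasta = fastaPath, gtf = gtfPath, sam = samPaths,
                   truth = truthPath, config = cfgPath,
                   truth_table = truth))
}
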