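#' @importFrom Biostrings getSeq IUPAC_CODE_MAP reverseComplement
#'   DNAStringSet
NULL

## Expand an IUPAC nucleotide character (DNA alphabet) to its base set.
.iupacBases <- function(chars) {
    map <- Biostrings::IUPAC_CODE_MAP
    idx <- match(chars, names(map))
    if (anyNA(idx))
        stop("non-IUPAC character in sequence: ",
             paste(unique(chars[is.na(idx)]), collapse = ", "))
    strsplit(unname(map[idx]), "", fixed = TRUE)
}

#' Scan an intron 3' region for a branch-point consensus
#'
#' Slides the consensus over the final \code{window} nt of an intron given
#' 5'->3' in transcript orientation, scoring each placement by the number of
#' IUPAC-compatible positions (simple match count, not a PWM: the motif of
#' interest is a single literal element). The nucleotide at the designated
#' branch position is reported, and flagged \code{noncanonical} when it is
#' not the canonical adenosine - the situation where splicing is expected to
#' lean on the U2 snRNA pseudouridine to stabilise an unconventional
#' U2:branch-site pair. Placements whose branch nucleotide falls in the last
#' 3 nt before the 3' splice site are excluded (branch points do not abut
#' the 3'SS). Hits with \code{score >= min_score} are returned sorted by
#' score (descending) and then proximity to the 3'SS, reflecting the
#' clustering of mammalian branch points around -18..-40.
#'
#' Both DNA (T) and RNA (U) spellings are accepted and normalised to RNA.
#'
#' @param intron_seq character or XString; intronic sequence, 5'->3' in
#'   transcript orientation (strand-resolved).
#' @param consensus IUPAC consensus (default \code{"UCCUGNC"}).
#' @param branch_pos position of the branch nucleotide within the consensus
#'   (default 6). Configurable because which motif position carries the
#'   branch A is annotation-dependent.
#' @param window number of 3'-terminal intron nt to scan (default 100);
#'   clipped with a warning when longer than the intron.
#' @param min_score minimum number of matching positions for a hit
#'   (default: full consensus length, i.e. exact matches only).
#' @return data.frame (offset_from_3ss, matched_seq, branch_nt, score,
#'   noncanonical); \code{offset_from_3ss} is the number of intronic bases
#'   3' of the branch nucleotide.
#' @export
scanBranchSite <- function(intron_seq, consensus = "UCCUGNC",
                           branch_pos = 6L, window = 100L,
                           min_score = nchar(consensus)) {
    seq <- toupper(as.character(intron_seq))
    if (length(seq) != 1L)
        stop("intron_seq must be a single sequence")
    cons <- chartr("U", "T", toupper(as.character(consensus)))
    cl <- nchar(cons)
    if (cl < 1L) stop("empty consensus")
    branch_pos <- as.integer(branch_pos)
    if (branch_pos < 1L || branch_pos > cl)
        stop("branch_pos must designate one consensus position")
    sch <- strsplit(chartr("U", "T", seq), "", fixed = TRUE)[[1L]]
    n <- length(sch)
    seqSets <- .iupacBases(sch)
    if (window > n) {
        warning("window (", window, " nt) longer than intron (", n,
                " nt); clipped")
        window <- n
    }
    if (window < cl)
        stop("window shorter than the consensus")
    consSets <- .iupacBases(strsplit(cons, "", fixed = TRUE)[[1L]])
    ## candidate start positions: match inside the window, fits in the
    ## sequence, branch nt not within the last 3 nt
    pmin_ <- max(1L, n - as.integer(window) + 1L)
    pmax_ <- min(n - cl + 1L, n - 3L - branch_pos + 1L)
    empty <- data.frame(offset_from_3ss = integer(),
                        matched_seq = character(),
                        branch_nt = character(), score = integer(),
                        noncanonical = logical())
    if (pmax_ < pmin_) return(empty)
    starts <- pmin_:pmax_
    score <- integer(length(starts))
    for (j in seq_len(cl)) {
        ok <- vapply(seqSets[starts + j - 1L],
                     function(s) all(s %in% consSets[[j]]), NA)
        score <- score + as.integer(ok)
    }
    hit <- score >= min_score
    if (!any(hit)) return(empty)
    starts <- starts[hit]
    score <- score[hit]
    rna <- chartr("T", "U", seq)
    branch_nt <- substring(rna, starts + branch_pos - 1L,
                           starts + branch_pos - 1L)
    out <- data.frame(
        offset_from_3ss = n - (starts + branch_pos - 1L),
        matched_seq = substring(rna, starts, starts + cl - 1L),
        branch_nt = branch_nt,
        score = score,
        noncanonical = branch_nt != "A")
    out <- out[order(-out$score, out$offset_from_3ss), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Extract strand-resolved intron sequences
#'
#' Fetches the intronic sequence of every junction from a genome FASTA,
#' reverse-complementing minus-strand introns so that all sequences read
#' 5'->3' in transcript orientation.
#'
#' @param catalog a [JunctionCatalog-class].
#' @param fasta path to the genome FASTA (an .fai index is created if
#'   missing).
#' @return DNAStringSet named by junction_id.
#' @export
intronSequences <- function(catalog, fasta) {
    stopifnot(is(catalog, "JunctionCatalog"))
    if (!file.exists(fasta))
        stop("FASTA file not found: ", fasta)
    if (!file.exists(paste0(fasta, ".fai")))
        Rsamtools::indexFa(fasta)
    fa <- Rsamtools::FaFile(fasta)
    intr <- intronRanges(catalog)
    seqs <- getSeq(fa, intr)  # getSeq honours strand
    names(seqs) <- intr$junction_id
    seqs
}

#' Branch-site scan over a whole junction catalog
#'
#' Applies [scanBranchSite()] to every intron of the catalog using sequences
#' extracted from a genome FASTA.
#'
#' @inheritParams intronSequences
#' @inheritParams scanBranchSite
#' @return data.frame with a leading junction_id column followed by the
#'   [scanBranchSite()] columns; zero rows for introns without hits.
#' @export
scanCatalogBranchSites <- function(catalog, fasta, consensus = "UCCUGNC",
                                   branch_pos = 6L, window = 100L,
                                   min_score = nchar(consensus)) {
    seqs <- intronSequences(catalog, fasta)
    res <- lapply(seq_along(seqs), function(i) {
        hits <- scanBranchSite(seqs[[i]], consensus = consensus,
                               branch_pos = branch_pos, window = window,
                               min_score = min_score)
        if (nrow(hits))
            cbind(junction_id = names(seqs)[i], hits)
        else NULL
    })
    res <- res[!vapply(res, is.null, NA)]
    if (length(res) == 0L)
        return(data.frame(junction_id = character(),
                          offset_from_3ss = integer(),
                          matched_seq = character(),
                          branch_nt = character(), score = integer(),
                          noncanonical = logical()))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
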