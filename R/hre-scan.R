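#' Scan nucleotide sequences for an IUPAC motif on both strands
#'
#' Reports every position where the forward-strand slice matches the motif
#' under IUPAC expansion (R = A/G, Y = C/T, N = any, ...) as a "+" hit and,
#' when \code{bothStrands}, every position where the slice matches the
#' reverse complement of the motif as a "-" hit. Overlapping hits are all
#' reported; coordinates are 1-based inclusive on the forward sequence and
#' the matched text is always the forward-strand slice. The default motif is
#' the hypoxia-response-element consensus 5'-RCGTG-3' bound by HIF.
#'
#' An \code{N} in the sequence never satisfies a non-N motif letter, so
#' ambiguous bases cannot inflate hit counts.
#'
#' @param seqs A \link[Biostrings]{DNAStringSet}, \code{DNAString}, or
#'   (named) character vector of sequences.
#' @param motif IUPAC pattern (default \code{"RCGTG"}).
#' @param bothStrands Also scan the reverse strand (default TRUE).
#'
#' @return data.frame with columns \code{seqId}, \code{start}, \code{end},
#'   \code{strand}, \code{match}, sorted by sequence, start, then strand.
#'
#' @examples
#' scanMotif(c(p1 = "ACGTGCACGT"))
#' @export
scanMotif <- function(seqs, motif = "RCGTG", bothStrands = TRUE) {
    if (is(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(seqs)
    if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
    if (!is.character(seqs)) stop("seqs must be sequences or character")
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("seq%d", seq_along(seqs))
    codes <- Biostrings::IUPAC_CODE_MAP
    motif <- toupper(motif)
    motifChars <- strsplit(motif, "")[[1L]]
    if (!length(motifChars)) stop("motif must be non-empty")
    bad <- setdiff(motifChars, names(codes))
    if (length(bad))
        stop("invalid IUPAC letter in motif: ", paste(bad, collapse = ", "))
    rcMotif <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))

    matchStarts <- function(chars, pattern) {
        m <- nchar(pattern)
        L <- length(chars)
        if (L < m) return(integer(0))
        pats <- strsplit(pattern, "")[[1L]]
        ok <- rep(TRUE, L - m + 1L)
        for (j in seq_len(m)) {
            sub <- chars[j:(L - m + j)]
            expand <- strsplit(codes[[pats[j]]], "")[[1L]]
            okj <- sub %in% expand & sub != "N"
            if (pats[j] == "N") okj <- okj | sub == "N"
            ok <- ok & okj
        }
        which(ok)
    }

    out <- list()
    m <- nchar(motif)
    for (i in seq_along(seqs)) {
        chars <- strsplit(toupper(seqs[[i]]), "")[[1L]]
        fwd <- matchStarts(chars, motif)
        starts <- fwd
        strands <- rep("+", length(fwd))
        if (bothStrands) {
            rev <- matchStarts(chars, rcMotif)
            starts <- c(starts, rev)
            strands <- c(strands, rep("-", length(rev)))
        }
        if (!length(starts)) next
        o <- order(starts, strands)
        starts <- starts[o]
        strands <- strands[o]
        out[[length(out) + 1L]] <- data.frame(
            seqId = names(seqs)[i], start = starts, end = starts + m - 1L,
            strand = strands,
            match = vapply(starts, function(s)
                paste(chars[s:(s + m - 1L)], collapse = ""), character(1)),
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(seqId = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          match = character(0), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Count motif hits fully contained in regions
#'
#' A hit is counted in a region only when it lies entirely inside it
#' (1-based inclusive coordinates); hits straddling a region edge are not
#' counted. Useful for tallying hypoxia-response elements per promoter,
#' 5'UTR or intron region.
#'
#' @param hits data.frame from \code{\link{scanMotif}}.
#' @param regions data.frame with columns \code{id}, \code{start},
#'   \code{end}, and optionally \code{seqId} to restrict a region to one
#'   sequence.
#'
#' @return data.frame with columns \code{id} and \code{count}, one row per
#'   region in input order.
#' @export
countHitsPerRegion <- function(hits, regions) {
    need <- c("id", "start", "end")
    if (!all(need %in% names(regions)))
        stop("regions must have columns id, start, end")
    if (any(regions$end < regions$start))
        stop("inverted region (end < start): ",
             regions$id[which(regions$end < regions$start)[1L]])
    counts <- integer(nrow(regions))
    if (nrow(hits)) {
        q <- IRanges::IRanges(start = hits$start, end = hits$end)
        s <- IRanges::IRanges(start = regions$start, end = regions$end)
        ov <- IRanges::findOverlaps(q, s, type = "within")
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        if ("seqId" %in% names(regions)) {
            keep <- hits$seqId[qh] == regions$seqId[sh]
            qh <- qh[keep]; sh <- sh[keep]
        }
        tab <- table(factor(sh, levels = seq_len(nrow(regions))))
        counts <- as.integer(tab)
    }
    data.frame(id = regions$id, count = counts, stringsAsFactors = FALSE)
}
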