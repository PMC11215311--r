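## Longest-ORF prediction on the transcript sense strand, genomic CDS
## mapping, and coding-region comparison between isoforms.

.STOPS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of a sequence
#'
#' Scans the sense strand in all three frames for ATG-initiated ORFs with
#' an in-frame stop codon. Any codon containing N is non-translatable and
#' an ORF cannot span it. The longest ORF wins; ties go to the 5'-most
#' start.
#'
#' @param seq A single sequence (character or `DNAString`) over
#'   A, C, G, T, N.
#' @param minLen Minimum ORF length in nucleotides including the stop codon
#'   (default 100, the usual long-read ORF-calling default). Use 0 to
#'   disable.
#' @return `NULL` when no qualifying ORF exists, else a list with `start`
#'   (0-based transcript offset of the A of ATG), `end` (0-based exclusive,
#'   after the stop codon) and `protein` (amino acids, stop excluded).
#' @export
longestOrf <- function(seq, minLen = 100L) {
    s <- toupper(as.character(seq))
    n <- nchar(s)
    best <- NULL
    for (frame in 0:2) {
        ncod <- (n - frame) %/% 3L
        if (ncod < 2L) next
        starts0 <- frame + 3L * (seq_len(ncod) - 1L)
        codons <- substring(s, starts0 + 1L, starts0 + 3L)
        isStart <- codons == "ATG"
        isStop <- codons %in% .STOPS
        hasN <- grepl("N", codons, fixed = TRUE)
        ## barriers: stops terminate, N codons break; scan segments between
        ## barriers, first ATG in a segment pairs with the terminating stop
        barrier <- which(isStop | hasN)
        segStart <- 1L
        for (b in c(barrier, ncod + 1L)) {
            if (b > ncod || hasN[b]) { segStart <- b + 1L; next }
            ## b is a stop codon; eligible starts in [segStart, b-1]
            cand <- if (b > segStart) which(isStart[segStart:(b - 1L)])
                    else integer(0)
            if (length(cand)) {
                i <- segStart + cand[1L] - 1L
                st <- starts0[i]; en <- starts0[b] + 3L
                len <- en - st
                if (len >= minLen &&
                    (is.null(best) || len > best$len ||
                     (len == best$len && st < best$start)))
                    best <- list(start = st, end = en, len = len)
            }
            segStart <- b + 1L
        }
    }
    if (is.null(best)) return(NULL)
    aa <- as.character(translate(DNAString(substr(s, best$start + 1L,
                                                  best$end - 3L))))
    list(start = best$start, end = best$end, protein = aa)
}

#' Map a transcript-coordinate ORF to genomic CDS intervals
#'
#' Converts `[start, end)` 0-based transcript coordinates into 1-based
#' inclusive genomic intervals partitioned across exons, strand-aware.
#' Extracting and splicing these intervals reproduces the ORF nucleotides.
#'
#' @param tx Single-transcript [TranscriptSet].
#' @param start,end 0-based half-open transcript coordinates (as returned
#'   by [longestOrf()]).
#' @return data.frame of genomic intervals (`start`, `end`), ascending.
#' @export
mapOrfToGenome <- function(tx, start, end) {
    t <- .plainTx(tx)[[1]]
    w <- t$ends - t$starts + 1L
    total <- sum(w)
    if (start < 0L || end > total || end <= start)
        stop("ORF outside spliced length for ", t$id)
    ## transcript-order exon list
    ord <- if (t$strand == "+") seq_along(w) else rev(seq_along(w))
    res <- list()
    pos <- 0L  # transcript offset consumed
    for (i in ord) {
        wi <- w[i]
        lo <- max(start, pos); hi <- min(end, pos + wi)
        if (lo < hi) {
            o1 <- lo - pos; o2 <- hi - pos  # offsets within this exon, 5'->3'
            if (t$strand == "+") {
                gs <- t$starts[i] + o1; ge <- t$starts[i] + o2 - 1L
            } else {
                ge <- t$ends[i] - o1; gs <- t$ends[i] - o2 + 1L
            }
            res[[length(res) + 1L]] <- c(gs, ge)
        }
        pos <- pos + wi
        if (pos >= end) break
    }
    m <- do.call(rbind, res)
    df <- data.frame(start = m[, 1], end = m[, 2])
    df[order(df$start), , drop = FALSE]
}

#' Predict ORFs for every transcript
#'
#' @param ts A [TranscriptSet].
#' @param genome `DNAStringSet` named by chromosome.
#' @param minLen Passed to [longestOrf()].
#' @return Named list per transcript: `NULL` when no ORF, else a list with
#'   `start`, `end`, `protein` and `cds` (genomic interval data.frame).
#' @export
predictOrfs <- function(ts, genome, minLen = 100L) {
    seqs <- splicedSequence(ts, genome)
    ids <- transcriptIds(ts)
    out <- vector("list", length(ids)); names(out) <- ids
    for (i in seq_along(ids)) {
        orf <- longestOrf(seqs[[i]], minLen = minLen)
        if (is.null(orf)) next
        orf$cds <- mapOrfToGenome(ts[ids[i]], orf$start, orf$end)
        out[[i]] <- orf
    }
    out
}

#' Do two isoforms differ in their protein-coding regions?
#'
#' TRUE when the protein sequences differ or the genomic CDS interval sets
#' differ (an isoform without an ORF differs from one with an ORF; two
#' isoforms both lacking ORFs do not differ).
#'
#' @param orfA,orfB Entries of [predictOrfs()] output (may be `NULL`).
#' @return Logical.
#' @export
codingRegionsDiffer <- function(orfA, orfB) {
    if (is.null(orfA) && is.null(orfB)) return(FALSE)
    if (is.null(orfA) || is.null(orfB)) return(TRUE)
    if (!identical(orfA$protein, orfB$protein)) return(TRUE)
    ca <- orfA$cds[order(orfA$cds$start), c("start", "end")]
    cb <- orfB$cds[order(orfB$cds$start), c("start", "end")]
    !(nrow(ca) == nrow(cb) && all(ca$start == cb$start) &&
      all(ca$end == cb$end))
}
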