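## Upstream regulatory-region extraction and PWM scanning with exact
## background p-values computed by dynamic programming over the discretised
## column score distributions.

.BASES <- c("A", "C", "G", "T")

#' Read motifs in JASPAR PFM text format
#'
#' Parses blocks of the form `>ID name` followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional) into
#' [PositionFrequencyMatrix] objects.
#'
#' @param path Motif file path.
#' @return Named list of `PositionFrequencyMatrix`.
#' @export
readJaspar <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    heads <- grep("^>", lines)
    if (!length(heads)) stop("no JASPAR records in ", path)
    out <- list()
    for (k in seq_along(heads)) {
        from <- heads[k] + 1L
        to <- if (k < length(heads)) heads[k + 1L] - 1L else length(lines)
        id <- strsplit(sub("^>\\s*", "", lines[heads[k]]), "\\s+")[[1]][1]
        block <- lines[from:to]
        if (length(block) != 4L)
            stop("motif ", id, ": expected 4 count rows")
        rows <- lapply(block, function(l) {
            l <- gsub("[][]", " ", l)
            parts <- strsplit(trimws(l), "\\s+")[[1]]
            if (parts[1] %in% .BASES) parts <- parts[-1]
            as.numeric(parts)
        })
        w <- unique(lengths(rows))
        if (length(w) != 1L) stop("motif ", id, ": ragged count rows")
        m <- do.call(rbind, rows)
        rownames(m) <- .BASES
        out[[id]] <- PositionFrequencyMatrix(id, m)
    }
    out
}

#' Write motifs in JASPAR PFM text format
#'
#' @param pfms List of [PositionFrequencyMatrix] (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeJaspar <- function(pfms, path) {
    if (is(pfms, "PositionFrequencyMatrix")) pfms <- list(pfms)
    con <- file(path, "w")
    on.exit(close(con))
    for (p in pfms) {
        writeLines(paste0(">", p@motifId), con)
        for (b in .BASES)
            writeLines(paste0(b, " [ ",
                              paste(p@counts[b, ], collapse = " "), " ]"),
                       con)
    }
    invisible(path)
}

#' Log-odds scoring matrix from a PFM
#'
#' `logOdds[b, j] = log2( (counts[b, j] + pc * bg[b]) /
#' (sum_b counts[b, j] + pc) / bg[b] )`.
#'
#' @param pfm A [PositionFrequencyMatrix].
#' @param background Base probabilities A, C, G, T (default uniform).
#' @param pseudocount Total pseudocount split by background (default 0.8,
#'   the common JASPAR practice).
#' @return A [MotifScoringMatrix].
#' @export
pfmToScoring <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
    if (any(background <= 0)) stop("background entries must be positive")
    background <- background / sum(background)
    m <- pfm@counts
    tot <- colSums(m)
    prob <- sweep(m + pseudocount * background, 2L, tot + pseudocount, "/")
    lo <- log2(prob / background)
    rownames(lo) <- .BASES
    new("MotifScoringMatrix", motifId = pfm@motifId, logOdds = lo,
        background = background, pseudocount = pseudocount)
}

## discretised distribution of the total score of a random background word.
## Columns are binned at binWidth / w so the accumulated rounding error of
## any word score stays below half of one output bin.
.scoreDistribution <- function(sm, binWidth = 1e-3) {
    w <- ncol(sm@logOdds)
    ibw <- binWidth / w
    B <- round(sm@logOdds / ibw)
    bg <- sm@background
    cur <- 1
    curLo <- 0L
    for (j in seq_len(w)) {
        newLo <- curLo + min(B[, j])
        newHi <- curLo + length(cur) - 1L + max(B[, j])
        nxt <- numeric(newHi - newLo + 1L)
        for (b in 1:4) {
            off <- curLo + B[b, j] - newLo
            idx <- seq_along(cur) + off
            nxt[idx] <- nxt[idx] + cur * bg[b]
        }
        cur <- nxt; curLo <- newLo
    }
    list(lo = curLo, probs = cur, binWidth = ibw, halfErr = binWidth / 2)
}

## upper-tail probability at a score. DP word scores are accurate to
## +/- halfErr, so the query is lowered by that much: the tail always
## includes the mass of every word whose true score is >= `score`
## (in particular the word's own probability), and overshoots by at most
## the mass within one output bin below it.
.tailAt <- function(dist, score) {
    bin <- ceiling((score - dist$halfErr) / dist$binWidth - 1e-9)
    tails <- rev(cumsum(rev(dist$probs)))
    i <- bin - dist$lo + 1L
    if (i <= 1L) return(1)
    if (i > length(tails)) return(0)
    tails[i]
}

#' Score threshold for a target p-value
#'
#' The smallest score `s` with `P(score(W) >= s) <= pCutoff` for a random
#' word drawn i.i.d. from the background, computed by dynamic programming
#' over the discretised per-column score distribution.
#'
#' @param sm A [MotifScoringMatrix].
#' @param pCutoff Target p-value (default 1e-5).
#' @param binWidth Discretisation bin (score units, default 1e-3).
#' @return Numeric threshold score. `pCutoff = 1` returns the minimum
#'   possible score; an unreachable cutoff returns just above the maximum.
#' @export
scoreThresholdForPvalue <- function(sm, pCutoff = 1e-5, binWidth = 1e-3) {
    dist <- .scoreDistribution(sm, binWidth)
    tails <- rev(cumsum(rev(dist$probs)))
    ok <- which(tails <= pCutoff + 1e-15)
    if (!length(ok))
        return((dist$lo + length(dist$probs)) * dist$binWidth)
    (dist$lo + ok[1L] - 1L) * dist$binWidth
}

#' Exact tail probability of a score
#'
#' `P(score(W) >= score)` for a background word, using the same DP
#' discretisation as [scoreThresholdForPvalue()] (agreement with full word
#' enumeration is within one bin).
#'
#' @inheritParams scoreThresholdForPvalue
#' @param score Observed log-odds score(s); vectorized.
#' @return Numeric p-value(s) in (0, 1].
#' @export
pwmTailProbability <- function(sm, score, binWidth = 1e-3) {
    dist <- .scoreDistribution(sm, binWidth)
    vapply(score, function(s) .tailAt(dist, s), numeric(1))
}

#' Exhaustive word enumeration of a PWM score distribution
#'
#' Reference implementation for validation: enumerates all `4^w` words,
#' their exact scores and background probabilities.
#'
#' @param sm A [MotifScoringMatrix] of width <= 10.
#' @return data.frame `score`, `prob`, sorted by descending score, plus a
#'   helper attribute `tail` (cumulative upper-tail probability).
#' @export
enumeratePwmWords <- function(sm) {
    w <- ncol(sm@logOdds)
    if (w > 10L) stop("enumeration limited to width <= 10")
    grid <- expand.grid(rep(list(1:4), w))
    score <- numeric(nrow(grid)); prob <- rep(1, nrow(grid))
    for (j in seq_len(w)) {
        score <- score + sm@logOdds[grid[, j], j]
        prob <- prob * sm@background[grid[, j]]
    }
    o <- order(-score)
    out <- data.frame(score = score[o], prob = prob[o])
    attr(out, "tail") <- cumsum(out$prob)
    out
}

## reverse-complement of a scoring matrix: swap A<->T, C<->G, reverse cols
.revcompMatrix <- function(lo) {
    rc <- lo[c("T", "G", "C", "A"), rev(seq_len(ncol(lo))), drop = FALSE]
    rownames(rc) <- .BASES
    rc
}

#' Scan a region with a PWM at a p-value cutoff
#'
#' Scores every window on both strands and reports hits whose score meets
#' the threshold for `pCutoff`; each hit carries its exact background
#' p-value. Windows containing N are skipped. All overlapping hits are
#' reported.
#'
#' @param region Region sequence (character or `DNAString`), already in the
#'   sense orientation of the gene.
#' @param sm A [MotifScoringMatrix].
#' @param pCutoff P-value cutoff (default 1e-5).
#' @param binWidth DP discretisation bin.
#' @return data.frame: `motif_id`, `offset` (1-based window start in the
#'   region), `strand` (relative to the region), `score`, `p_value`.
#' @export
scanRegion <- function(region, sm, pCutoff = 1e-5, binWidth = 1e-3) {
    s <- toupper(as.character(region))
    w <- ncol(sm@logOdds)
    L <- nchar(s)
    empty <- data.frame(motif_id = character(0), offset = integer(0),
                        strand = character(0), score = numeric(0),
                        p_value = numeric(0))
    if (L < w) return(empty)
    dist <- .scoreDistribution(sm, binWidth)
    tails <- rev(cumsum(rev(dist$probs)))
    ok <- which(tails <= pCutoff + 1e-15)
    thr <- if (length(ok)) (dist$lo + ok[1L] - 1L) * dist$binWidth else Inf
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], .BASES)
    nwin <- L - w + 1L
    scoreWith <- function(lo) {
        sc <- numeric(nwin)
        bad <- logical(nwin)
        for (j in seq_len(w)) {
            cj <- code[seq_len(nwin) + j - 1L]
            bad <- bad | is.na(cj)
            v <- lo[cbind(ifelse(is.na(cj), 1L, cj), j)]
            sc <- sc + v
        }
        sc[bad] <- NA_real_
        sc
    }
    fw <- scoreWith(sm@logOdds)
    rv <- scoreWith(.revcompMatrix(sm@logOdds))
    hitRows <- function(sc, strand) {
        ## prefilter by score (one-bin slack), then accept on the
        ## conservative tail probability itself
        i <- which(!is.na(sc) & sc >= thr - binWidth - 1e-12)
        if (!length(i)) return(NULL)
        pv <- vapply(sc[i], function(x) .tailAt(dist, x), numeric(1))
        keep <- pv <= pCutoff + 1e-15
        i <- i[keep]; pv <- pv[keep]
        if (!length(i)) return(NULL)
        data.frame(motif_id = sm@motifId, offset = i, strand = strand,
                   score = sc[i], p_value = pv)
    }
    out <- rbind(hitRows(fw, "+"), hitRows(rv, "-"))
    if (is.null(out)) return(empty)
    out <- out[order(out$offset, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Extract candidate upstream regulatory regions
#'
#' For each gene, selects the longest isoform (by spliced length, ties by
#' id), requires a predicted ORF for it, and extracts the genomic
#' (unspliced) sequence from `flank` bp upstream of its transcription start
#' site through the base immediately before the first base of the start
#' codon, clipped at chromosome ends with a warning; minus-strand regions
#' are reverse-complemented (gene-sense orientation).
#'
#' @param ts A [TranscriptSet].
#' @param genome `DNAStringSet` named by chromosome.
#' @param orfs Output of [predictOrfs()] covering at least the longest
#'   isoform per gene of interest.
#' @param genes Genes to process (default: all in `ts`).
#' @param flank Upstream flank in bp (default 5000).
#' @return data.frame: `gene_id`, `isoform_id`, `chrom`, `strand`, `start`,
#'   `end` (genomic, 1-based inclusive) and `sequence` (sense orientation).
#'   Genes whose longest isoform lacks an ORF are skipped with a warning.
#' @export
extractUpstream <- function(ts, genome, orfs, genes = NULL, flank = 5000L) {
    gid <- geneIds(ts)
    if (is.null(genes)) genes <- sort(unique(gid))
    lens <- splicedLength(ts)
    plain <- .plainTx(ts)
    rows <- list()
    for (g in genes) {
        ids <- names(gid)[gid == g]
        ids <- ids[order(-lens[ids], ids)]
        iso <- ids[1L]
        orf <- orfs[[iso]]
        if (is.null(orf)) {
            warning("gene ", g, ": longest isoform ", iso,
                    " has no ORF; skipped")
            next
        }
        t <- plain[[iso]]
        chr <- genome[[t$chrom]]
        if (t$strand == "+") {
            tss <- min(t$starts)
            cdsFirst <- min(orf$cds$start)
            lo <- tss - flank; hi <- cdsFirst - 1L
            if (lo < 1L) {
                warning("gene ", g, ": upstream region clipped at chromosome start")
                lo <- 1L
            }
            if (hi < lo) {
                warning("gene ", g, ": empty upstream region; skipped")
                next
            }
            sq <- as.character(subseq(chr, lo, hi))
        } else {
            tss <- max(t$ends)
            cdsFirst <- max(orf$cds$end)
            lo <- cdsFirst + 1L; hi <- tss + flank
            if (hi > length(chr)) {
                warning("gene ", g, ": upstream region clipped at chromosome end")
                hi <- length(chr)
            }
            if (hi < lo) {
                warning("gene ", g, ": empty upstream region; skipped")
                next
            }
            sq <- as.character(reverseComplement(subseq(chr, lo, hi)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, isoform_id = iso, chrom = t$chrom,
            strand = t$strand, start = lo, end = hi, sequence = sq)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_id = character(0), isoform_id = character(0),
                   chrom = character(0), strand = character(0),
                   start = integer(0), end = integer(0),
                   sequence = character(0))
    rownames(out) <- NULL
    out
}

#' Scan all upstream regions with a set of motifs
#'
#' @param regions Output of [extractUpstream()].
#' @param motifs List of [MotifScoringMatrix] (or PFMs, converted with
#'   defaults).
#' @param pCutoff,binWidth Passed to [scanRegion()].
#' @return data.frame of hits with `gene_id` attached.
#' @export
scanUpstreamRegions <- function(regions, motifs, pCutoff = 1e-5,
                                binWidth = 1e-3) {
    motifs <- lapply(motifs, function(m)
        if (is(m, "PositionFrequencyMatrix")) pfmToScoring(m) else m)
    rows <- list()
    for (i in seq_len(nrow(regions))) {
        for (sm in motifs) {
            h <- scanRegion(regions$sequence[i], sm, pCutoff = pCutoff,
                            binWidth = binWidth)
            if (nrow(h)) {
                h$gene_id <- regions$gene_id[i]
                rows[[length(rows) + 1L]] <- h
            }
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(motif_id = character(0), offset = integer(0),
                   strand = character(0), score = numeric(0),
                   p_value = numeric(0), gene_id = character(0))
    rownames(out) <- NULL
    out
}

#' Filter candidate transcription factors by antennal expression
#'
#' Keeps TFs whose hit motifs map to genes with TPM above `minTPM` in
#' female or male samples (strict inequality). TFs without an expression
#' record are dropped with a warning.
#'
#' @param hits Motif hits with a `motif_id` column (e.g. from
#'   [scanUpstreamRegions()]).
#' @param tfExpression data.frame with columns `motif_id`, `tf_gene_id`,
#'   `tpm_female`, `tpm_male`.
#' @param minTPM Expression threshold (default 20).
#' @return data.frame of candidate TFs: `motif_id`, `tf_gene_id`,
#'   `tpm_female`, `tpm_male`, `n_hits`.
#' @export
filterTFCandidates <- function(hits, tfExpression, minTPM = 20) {
    ids <- unique(hits$motif_id)
    miss <- setdiff(ids, tfExpression$motif_id)
    if (length(miss))
        warning("no expression record for motif(s): ",
                paste(miss, collapse = ", "), "; dropped")
    tf <- tfExpression[tfExpression$motif_id %in% ids, , drop = FALSE]
    keep <- tf$tpm_female > minTPM | tf$tpm_male > minTPM
    tf <- tf[keep, , drop = FALSE]
    tf$n_hits <- vapply(tf$motif_id, function(m)
        sum(hits$motif_id == m), integer(1))
    rownames(tf) <- NULL
    tf
}
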