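#' Read transcript models from a GTF file
#'
#' Parses the `exon` features of a GTF file (1-based inclusive coordinates,
#' attributes `gene_id` and `transcript_id`) into a [TranscriptSet]. Exons
#' are merged and sorted per transcript; a transcript whose exons span more
#' than one chromosome or strand is rejected.
#'
#' @param path Path to a GTF file.
#' @return A [TranscriptSet].
#' @seealso [writeGTF()]
#' @export
readGTF <- function(path) {
    lines <- readLines(path)
    body <- which(!grepl("^\\s*(#|$)", lines))
    if (length(body)) {
        nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
        bad <- body[nf < 9L]
        if (length(bad))
            stop("malformed GTF line ", bad[1], " in ", path,
                 " (expected 9 tab-separated fields)")
    }
    if (!length(body)) {
        return(new("TranscriptSet", exons = GRangesList(),
                   geneId = setNames(character(0), character(0))))
    }
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[mcols(gr)$type == "exon"]
    if (!length(gr))
        return(new("TranscriptSet", exons = GRangesList(),
                   geneId = setNames(character(0), character(0))))
    md <- mcols(gr)
    if (is.null(md$gene_id) || is.null(md$transcript_id) ||
        anyNA(md$gene_id) || anyNA(md$transcript_id))
        stop("GTF exons must carry gene_id and transcript_id attributes")
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     strand = as.character(strand(gr)),
                     transcript_id = md$transcript_id,
                     gene_id = md$gene_id)
    if (any(df$strand == "*"))
        stop("GTF exons must be stranded (+/-)")
    mixed <- tapply(paste(df$chrom, df$strand), df$transcript_id,
                    function(x) length(unique(x)))
    if (any(mixed > 1L))
        stop("transcript(s) with exons on mixed chromosomes/strands: ",
             paste(names(mixed)[mixed > 1L], collapse = ", "))
    TranscriptSet(df)
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` row per exon (1-based inclusive) with `gene_id` and
#' `transcript_id` attributes, such that `readGTF(writeGTF(x))` reproduces
#' `x` exactly.
#'
#' @param ts A [TranscriptSet].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGTF <- function(ts, path) {
    if (!length(ts)) {
        writeLines("#gtf", path)
        return(invisible(path))
    }
    e <- ts@exons
    n <- elementNROWS(e)
    gr <- BiocGenerics::unlist(e, use.names = FALSE)
    mcols(gr)$source <- "isoswitch"
    mcols(gr)$type <- "exon"
    mcols(gr)$transcript_id <- rep(names(e), n)
    mcols(gr)$gene_id <- rep(unname(ts@geneId), n)
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

#' Read a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that truncates
#' sequence names at the first whitespace (the usual chromosome-id
#' convention).
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet` named by chromosome id.
#' @export
readGenome <- function(path) {
    g <- readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g))) stop("duplicate chromosome ids in ", path)
    g
}

#' Splice junctions of each transcript
#'
#' Returns, per transcript, the `n_exons - 1` splice junctions in
#' transcription order (5' to 3' of the transcript, i.e. reversed genomic
#' order on the minus strand). `donor` is the last exonic base before the
#' intron and `acceptor` the first exonic base after it, both 1-based
#' genomic positions.
#'
#' @param ts A [TranscriptSet].
#' @return A named list of data.frames with columns `donor`, `acceptor`
#'   (zero rows for mono-exon transcripts).
#' @export
junctionChain <- function(ts) {
    plain <- .plainTx(ts)
    lapply(plain, function(t) {
        n <- length(t$starts)
        if (n < 2L)
            return(data.frame(donor = integer(0), acceptor = integer(0)))
        d <- t$ends[-n]; a <- t$starts[-1L]
        if (t$strand == "-") {
            # transcription runs right to left: donor is the genomic start
            # of the downstream (rightmost) exon side of each intron
            df <- data.frame(donor = rev(a), acceptor = rev(d))
        } else {
            df <- data.frame(donor = d, acceptor = a)
        }
        df
    })
}

#' Group transcripts into gene loci
#'
#' Loci are taken from the `gene_id` carried by the input models (no
#' overlap-based regrouping). A gene whose transcripts span more than one
#' chromosome or strand is rejected.
#'
#' @param ts A [TranscriptSet].
#' @return A named list of [TranscriptSet] objects, one per gene, plus a
#'   `multi_isoform` attribute flagging loci with >= 2 transcripts.
#' @export
groupLoci <- function(ts) {
    ids <- transcriptIds(ts)
    genes <- ts@geneId
    ch <- txChrom(ts); sd <- txStrand(ts)
    key <- tapply(paste(ch, sd), genes, function(x) length(unique(x)))
    if (any(key > 1L))
        stop("gene_id spanning two chromosomes/strands: ",
             paste(names(key)[key > 1L], collapse = ", "))
    split_ids <- split(ids, genes)
    out <- lapply(split_ids, function(i) ts[i])
    attr(out, "multi_isoform") <- vapply(out, function(l) length(l) >= 2L,
                                         logical(1))
    out
}

#' Pair gene loci shared between two transcript sets
#'
#' A pair of loci is shared when their exonic intervals overlap by at least
#' one base on the same chromosome and strand. Pairing is one-to-one by
#' largest exonic overlap; ties are broken lexicographically by gene id.
#'
#' @param lociA,lociB Lists of [TranscriptSet] loci as returned by
#'   [groupLoci()].
#' @return data.frame with columns `gene_a`, `gene_b`, `overlap_bp`.
#' @export
sharedLoci <- function(lociA, lociB) {
    exonUnion <- function(l) reduce(BiocGenerics::unlist(exonRanges(l),
                                                         use.names = FALSE))
    ua <- lapply(lociA, exonUnion)
    ub <- lapply(lociB, exonUnion)
    if (!length(ua) || !length(ub))
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          overlap_bp = integer(0)))
    grA <- BiocGenerics::unlist(GRangesList(ua), use.names = FALSE)
    grB <- BiocGenerics::unlist(GRangesList(ub), use.names = FALSE)
    ia <- rep(seq_along(ua), elementNROWS(GRangesList(ua)))
    ib <- rep(seq_along(ub), elementNROWS(GRangesList(ub)))
    hits <- findOverlaps(grA, grB)
    if (!length(hits))
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          overlap_bp = integer(0)))
    qa <- ia[S4Vectors::queryHits(hits)]
    qb <- ib[S4Vectors::subjectHits(hits)]
    ov <- width(IRanges::pintersect(IRanges(start(grA), end(grA))[S4Vectors::queryHits(hits)],
                                    IRanges(start(grB), end(grB))[S4Vectors::subjectHits(hits)]))
    agg <- rowsum(ov, paste(qa, qb, sep = "\r"))
    keys <- strsplit(rownames(agg), "\r", fixed = TRUE)
    cand <- data.frame(
        gene_a = names(ua)[as.integer(vapply(keys, `[`, "", 1))],
        gene_b = names(ub)[as.integer(vapply(keys, `[`, "", 2))],
        overlap_bp = as.integer(agg[, 1]))
    # greedy one-to-one assignment by descending overlap, then gene ids
    cand <- cand[order(-cand$overlap_bp, pmin(cand$gene_a, cand$gene_b),
                       pmax(cand$gene_a, cand$gene_b)), ]
    keep <- logical(nrow(cand))
    seenA <- character(0); seenB <- character(0)
    for (i in seq_len(nrow(cand))) {
        if (!(cand$gene_a[i] %in% seenA) && !(cand$gene_b[i] %in% seenB)) {
            keep[i] <- TRUE
            seenA <- c(seenA, cand$gene_a[i])
            seenB <- c(seenB, cand$gene_b[i])
        }
    }
    out <- cand[keep, ]
    out <- out[order(out$gene_a), ]
    rownames(out) <- NULL
    out
}

#' Spliced transcript sequence
#'
#' Concatenates the exonic genome sequence of each transcript in
#' transcription order (reverse-complemented on the minus strand), giving
#' the RNA-sense DNA sequence.
#'
#' @param ts A [TranscriptSet].
#' @param genome A `DNAStringSet` named by chromosome.
#' @return A `DNAStringSet` named by transcript id.
#' @export
splicedSequence <- function(ts, genome) {
    plain <- .plainTx(ts)
    out <- vector("list", length(plain))
    for (i in seq_along(plain)) {
        t <- plain[[i]]
        chr <- genome[[t$chrom]]
        if (is.null(chr)) stop("chromosome not in genome: ", t$chrom)
        if (any(t$starts < 1L) || any(t$ends > length(chr)))
            stop("exon out of chromosome bounds for transcript ", t$id)
        seqs <- lapply(seq_along(t$starts),
                       function(j) subseq(chr, t$starts[j], t$ends[j]))
        s <- do.call(Biostrings::xscat, seqs)
        if (t$strand == "-") s <- reverseComplement(s)
        out[[i]] <- s
    }
    res <- DNAStringSet(out)
    names(res) <- names(plain)
    res
}

#' Spliced length and GC content summary
#'
#' Spliced length is the sum of exon lengths; GC is (G+C)/(A+C+G+T) over
#' the spliced sequence, with N excluded from the denominator (`NA` when
#' the sequence is all N).
#'
#' @param ts A [TranscriptSet].
#' @param genome A `DNAStringSet` named by chromosome.
#' @return data.frame with columns `transcript_id`, `length`, `gc`.
#' @export
lengthGCSummary <- function(ts, genome) {
    seqs <- splicedSequence(ts, genome)
    freq <- letterFrequency(seqs, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
    data.frame(transcript_id = names(seqs),
               length = unname(splicedLength(ts)),
               gc = unname(gc),
               row.names = NULL)
}

#' Mirror transcript coordinates
#'
#' Reflects every transcript through the point `mirror` (position `p`
#' becomes `mirror - p`) and flips the strand: the reverse-complement view
#' of a locus. Used by the strand-covariance properties of the event
#' annotator.
#'
#' @param ts A [TranscriptSet].
#' @param mirror Integer reflection constant (must exceed the largest
#'   coordinate).
#' @return A [TranscriptSet].
#' @export
reflectTranscripts <- function(ts, mirror) {
    plain <- .plainTx(ts)
    plain <- lapply(plain, function(t) {
        ns <- mirror - rev(t$ends)
        ne <- mirror - rev(t$starts)
        if (any(ns < 1L)) stop("mirror constant too small")
        t$starts <- ns; t$ends <- ne
        t$strand <- if (t$strand == "+") "-" else "+"
        t
    })
    .fromPlainTx(plain)
}
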