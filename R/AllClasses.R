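#' @import methods
#' @importFrom stats p.adjust pt rnbinom rpois rlnorm runif setNames
#' @importFrom utils combn read.delim write.table head tail
#' @importFrom S4Vectors DataFrame mcols mcols<- elementNROWS
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps reduce strand seqnames
#' @importFrom BiocGenerics start end width unlist
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement translate subseq replaceAt
#'   letterFrequency
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' TranscriptSet: a set of strand-aware exon-chain transcript models
#'
#' The central container of the package. Each transcript is an ordered,
#' disjoint exon chain on a single chromosome and strand, stored as a
#' [GenomicRanges::GRangesList] (one `GRanges` of exons per transcript,
#' 1-based inclusive coordinates, ascending genomic order), plus a parent
#' gene identifier per transcript.
#'
#' @slot exons A `GRangesList`, names are transcript identifiers.
#' @slot geneId Character vector of gene identifiers, parallel to `exons`
#'   and carrying the same names.
#' @export
setClass("TranscriptSet",
         slots = c(exons = "GRangesList", geneId = "character"))

setValidity("TranscriptSet", function(object) {
    e <- object@exons
    msg <- character(0)
    if (length(e) && (is.null(names(e)) || anyDuplicated(names(e))))
        msg <- c(msg, "transcript names must be present and unique")
    if (length(object@geneId) != length(e))
        msg <- c(msg, "geneId must be parallel to exons")
    if (length(e) && !identical(names(object@geneId), names(e)))
        msg <- c(msg, "geneId names must match transcript names")
    if (any(elementNROWS(e) < 1L))
        msg <- c(msg, "every transcript needs at least one exon")
    if (length(e)) {
        sp <- BiocGenerics::unlist(range(e), use.names = FALSE)
        if (length(sp) != length(e))
            msg <- c(msg, "each transcript must lie on one chromosome and strand")
        st <- start(e); en <- end(e)
        # exons sorted ascending, disjoint, separated by >= 1 bp intron
        bad <- any(unlist(lapply(seq_along(e), function(i) {
            s <- st[[i]]; x <- en[[i]]
            any(x < s) || (length(s) > 1L && any(s[-1L] <= x[-length(x)] + 1L))
        })))
        if (bad)
            msg <- c(msg, "exons must be ascending, disjoint and non-abutting")
        if (length(sp) == length(e) && any(as.character(strand(sp)) == "*"))
            msg <- c(msg, "strand must be + or -")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons Either a `GRangesList` (names = transcript ids) or a
#'   data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id` (one row per exon, 1-based inclusive).
#' @param geneId Named character vector mapping transcript id to gene id;
#'   ignored (derived) when `exons` is a data.frame.
#' @return A `TranscriptSet`.
#' @examples
#' df <- data.frame(chrom = "chr1", start = c(101, 201), end = c(150, 300),
#'                  strand = "+", transcript_id = "tx1", gene_id = "g1")
#' ts <- TranscriptSet(df)
#' splicedLength(ts)
#' @export
TranscriptSet <- function(exons, geneId = NULL) {
    if (is.data.frame(exons)) {
        req <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
        if (!all(req %in% names(exons)))
            stop("exon data.frame needs columns: ", paste(req, collapse = ", "))
        g2t <- tapply(as.character(exons$gene_id),
                      as.character(exons$transcript_id),
                      function(g) unique(g))
        if (any(lengths(g2t) != 1L))
            stop("a transcript maps to more than one gene_id")
        gr <- GRanges(seqnames = as.character(exons$chrom),
                      ranges = IRanges(exons$start, exons$end),
                      strand = as.character(exons$strand))
        grl <- S4Vectors::split(gr, as.character(exons$transcript_id))
        grl <- reduce(grl)
        geneId <- vapply(g2t, identity, character(1))[names(grl)]
        names(geneId) <- names(grl)
        exons <- grl
    } else {
        if (is.null(geneId)) stop("geneId required with a GRangesList")
        exons <- reduce(exons)
        geneId <- geneId[names(exons)]
    }
    new("TranscriptSet", exons = exons, geneId = geneId)
}

#' @describeIn TranscriptSet Number of transcripts.
#' @param x A `TranscriptSet`.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", length(object), "transcripts over",
        length(unique(object@geneId)), "genes\n")
    if (length(object)) {
        n <- min(5L, length(object))
        ids <- names(object@exons)[seq_len(n)]
        cat("  ", paste(ids, collapse = ", "),
            if (length(object) > n) "..." else "", "\n")
    }
})

#' Accessors for TranscriptSet
#'
#' `transcriptIds` and `geneIds` return the transcript/gene identifiers;
#' `exonRanges` the underlying `GRangesList`; `splicedLength` the per
#' transcript sum of exon widths; `txStrand`/`txChrom` the strand and
#' chromosome of each transcript.
#'
#' @param x A `TranscriptSet` (or, for `geneIds`, an `IsoformExperiment`).
#' @return Vectors named by transcript id (a `GRangesList` for
#'   `exonRanges`).
#' @name transcript-accessors
NULL

#' @rdname transcript-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname transcript-accessors
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@exons))

#' @rdname transcript-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname transcript-accessors
#' @export
setMethod("geneIds", "TranscriptSet", function(x) x@geneId)

#' @rdname transcript-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname transcript-accessors
#' @export
setMethod("exonRanges", "TranscriptSet", function(x) x@exons)

#' @rdname transcript-accessors
#' @export
setGeneric("splicedLength", function(x) standardGeneric("splicedLength"))
#' @rdname transcript-accessors
#' @export
setMethod("splicedLength", "TranscriptSet", function(x) {
    setNames(vapply(width(x@exons), sum, numeric(1)), names(x@exons))
})

#' @rdname transcript-accessors
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))
#' @rdname transcript-accessors
#' @export
setMethod("txStrand", "TranscriptSet", function(x) {
    sp <- BiocGenerics::unlist(range(x@exons), use.names = FALSE)
    setNames(as.character(strand(sp)), names(x@exons))
})

#' @rdname transcript-accessors
#' @export
setGeneric("txChrom", function(x) standardGeneric("txChrom"))
#' @rdname transcript-accessors
#' @export
setMethod("txChrom", "TranscriptSet", function(x) {
    sp <- BiocGenerics::unlist(range(x@exons), use.names = FALSE)
    setNames(as.character(seqnames(sp)), names(x@exons))
})

#' @param i Transcript ids (character) or indices.
#' @rdname transcript-accessors
#' @export
setMethod("[", "TranscriptSet", function(x, i) {
    ## plain slot copy: subsetting cannot invalidate a valid object, so the
    ## validity machinery is deliberately not re-run (it is O(n) per call)
    x@exons <- x@exons[i]
    x@geneId <- x@geneId[i]
    x
})

## internal: plain-list view used by the algorithmic core.
## Each element: list(id, gene, chrom, strand, starts, ends)
.plainTx <- function(ts) {
    e <- ts@exons
    if (!length(e)) return(list())
    st <- as.list(start(e)); en <- as.list(end(e))
    sp <- BiocGenerics::unlist(range(e), use.names = FALSE)
    ch <- as.character(seqnames(sp)); sd <- as.character(strand(sp))
    ids <- names(e); gn <- ts@geneId
    out <- vector("list", length(e))
    for (i in seq_along(e)) {
        out[[i]] <- list(id = ids[i], gene = unname(gn[i]), chrom = ch[i],
                         strand = sd[i], starts = st[[i]], ends = en[[i]])
    }
    names(out) <- ids
    out
}

## internal: rebuild a TranscriptSet from a plain list
.fromPlainTx <- function(plain) {
    if (!length(plain)) {
        return(new("TranscriptSet",
                   exons = GRangesList(),
                   geneId = setNames(character(0), character(0))))
    }
    n <- vapply(plain, function(t) length(t$starts), integer(1))
    df <- data.frame(
        chrom = rep(vapply(plain, `[[`, character(1), "chrom"), n),
        start = unlist(lapply(plain, `[[`, "starts")),
        end = unlist(lapply(plain, `[[`, "ends")),
        strand = rep(vapply(plain, `[[`, character(1), "strand"), n),
        transcript_id = rep(vapply(plain, `[[`, character(1), "id"), n),
        gene_id = rep(vapply(plain, `[[`, character(1), "gene"), n))
    TranscriptSet(df)
}

#' IsoformExperiment: isoform counts with gene map, lengths and design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' an isoform-level count matrix (`assay "counts"`), `rowData` columns
#' `gene_id` and `effective_length`, and a `colData` column `sex` with
#' levels `Female`/`Male`.
#'
#' @export
setClass("IsoformExperiment", contains = "SummarizedExperiment")

setValidity("IsoformExperiment", function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' required")
    else if (any(assay(object, "counts") < 0))
        msg <- c(msg, "counts must be non-negative")
    rd <- rowData(object)
    if (!all(c("gene_id", "effective_length") %in% colnames(rd)))
        msg <- c(msg, "rowData needs gene_id and effective_length")
    else if (any(rd$effective_length <= 0))
        msg <- c(msg, "effective_length must be positive")
    cd <- colData(object)
    if (!"sex" %in% colnames(cd))
        msg <- c(msg, "colData needs a sex column")
    else if (!all(as.character(cd$sex) %in% c("Female", "Male")))
        msg <- c(msg, "sex must be Female or Male")
    if (length(msg)) msg else TRUE
})

#' Construct an IsoformExperiment
#'
#' @param counts Numeric matrix of non-negative read counts, rows = isoforms
#'   (rownames = isoform ids), columns = samples (colnames = sample ids).
#' @param geneId Character vector of parent gene ids, one per isoform.
#' @param effectiveLength Positive numeric vector, one per isoform.
#' @param sex Character/factor of `"Female"`/`"Male"`, one per sample.
#' @return An `IsoformExperiment`.
#' @examples
#' cnt <- matrix(rpois(8, 50), 2, 4,
#'               dimnames = list(c("t1", "t2"), paste0("s", 1:4)))
#' ie <- IsoformExperiment(cnt, geneId = c("g1", "g1"),
#'                         effectiveLength = c(1000, 1500),
#'                         sex = c("Female", "Female", "Male", "Male"))
#' @export
IsoformExperiment <- function(counts, geneId, effectiveLength, sex) {
    se <- SummarizedExperiment(
        assays = list(counts = as.matrix(counts)),
        rowData = DataFrame(gene_id = as.character(geneId),
                            effective_length = as.numeric(effectiveLength)),
        colData = DataFrame(sex = factor(as.character(sex),
                                         levels = c("Female", "Male"))))
    new("IsoformExperiment", se)
}

#' @rdname transcript-accessors
#' @export
setMethod("geneIds", "IsoformExperiment", function(x)
    setNames(rowData(x)$gene_id, rownames(x)))

#' @rdname IsoformExperiment-class
#' @param x An `IsoformExperiment`.
#' @export
effectiveLength <- function(x) setNames(rowData(x)$effective_length, rownames(x))

#' @rdname IsoformExperiment-class
#' @export
sampleSex <- function(x) setNames(as.character(colData(x)$sex), colnames(x))

#' PositionFrequencyMatrix: motif base counts
#'
#' @slot motifId Motif identifier.
#' @slot counts 4 x w non-negative matrix with rownames A, C, G, T.
#' @export
setClass("PositionFrequencyMatrix",
         slots = c(motifId = "character", counts = "matrix"))

setValidity("PositionFrequencyMatrix", function(object) {
    m <- object@counts
    msg <- character(0)
    if (!identical(rownames(m), c("A", "C", "G", "T")))
        msg <- c(msg, "counts rows must be A, C, G, T")
    if (ncol(m) < 1L) msg <- c(msg, "width must be >= 1")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (ncol(m) >= 1L && any(colSums(m) <= 0))
        msg <- c(msg, "every column needs a positive count")
    if (length(msg)) msg else TRUE
})

#' @rdname PositionFrequencyMatrix-class
#' @param motifId,counts See slots.
#' @export
PositionFrequencyMatrix <- function(motifId, counts) {
    counts <- as.matrix(counts)
    rownames(counts) <- c("A", "C", "G", "T")
    new("PositionFrequencyMatrix", motifId = motifId, counts = counts)
}

setMethod("show", "PositionFrequencyMatrix", function(object) {
    cat("PositionFrequencyMatrix", object@motifId,
        "width", ncol(object@counts), "\n")
})

#' MotifScoringMatrix: log-odds matrix derived from a PFM
#'
#' @slot motifId Motif identifier.
#' @slot logOdds 4 x w real matrix (log2 odds vs background).
#' @slot background Background base probabilities (A, C, G, T), summing to 1.
#' @slot pseudocount Pseudocount used in the derivation.
#' @export
setClass("MotifScoringMatrix",
         slots = c(motifId = "character", logOdds = "matrix",
                   background = "numeric", pseudocount = "numeric"))

setValidity("MotifScoringMatrix", function(object) {
    msg <- character(0)
    if (!identical(rownames(object@logOdds), c("A", "C", "G", "T")))
        msg <- c(msg, "logOdds rows must be A, C, G, T")
    if (length(object@background) != 4L || any(object@background <= 0) ||
        abs(sum(object@background) - 1) > 1e-8)
        msg <- c(msg, "background must be 4 positive probabilities summing to 1")
    if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be > 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MotifScoringMatrix", function(object) {
    cat("MotifScoringMatrix", object@motifId, "width", ncol(object@logOdds),
        "| max score", round(sum(apply(object@logOdds, 2, max)), 3), "\n")
})
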