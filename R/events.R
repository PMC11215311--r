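## Alternative-splicing event annotation on ordered isoform pairs.
##
## Seven event types are recognised on a pair of isoforms from one locus:
## IR (intron retention), ES (exon skipping), MES (mutually exclusive
## exons), A5/A3 (alternative donor/acceptor at a shared exon boundary),
## ATSS/ATTS (alternative transcription start/termination). Differences
## between the two exon chains are decomposed into maximal genomic regions
## exonic in exactly one isoform; each region receives exactly one type,
## with precedence IR > ES/MES > A5/A3 > ATSS/ATTS.

.EVENT_TYPES <- c("A3", "A5", "ATSS", "ATTS", "ES", "IR", "MES")

.emptyEvents <- function() {
    data.frame(gene_id = character(0), isoform_a = character(0),
               isoform_b = character(0), event_type = character(0),
               region_start = integer(0), region_end = integer(0),
               regions = character(0), owner = character(0),
               in_coding_region = logical(0))
}

## maximal regions exonic in exactly one of a/b:
## data.frame(start, end, owner in {"a","b"}), ascending
.diffRegions <- function(a, b) {
    bp <- sort(unique(c(a$starts, a$ends + 1L, b$starts, b$ends + 1L)))
    s <- bp[-length(bp)]; e <- bp[-1L] - 1L
    inx <- function(t, p)
        vapply(p, function(q) any(t$starts <= q & q <= t$ends), logical(1))
    ina <- inx(a, s); inb <- inx(b, s)
    own <- ifelse(ina & !inb, "a", ifelse(inb & !ina, "b", NA))
    keep <- !is.na(own)
    if (!any(keep))
        return(data.frame(start = integer(0), end = integer(0),
                          owner = character(0)))
    s <- s[keep]; e <- e[keep]; own <- own[keep]
    out <- list(); cs <- s[1]; ce <- e[1]; co <- own[1]
    for (i in seq_along(s)[-1]) {
        if (own[i] == co && s[i] == ce + 1L) {
            ce <- e[i]
        } else {
            out[[length(out) + 1L]] <- c(cs, ce, co)
            cs <- s[i]; ce <- e[i]; co <- own[i]
        }
    }
    out[[length(out) + 1L]] <- c(cs, ce, co)
    data.frame(start = as.integer(vapply(out, `[`, "", 1)),
               end = as.integer(vapply(out, `[`, "", 2)),
               owner = vapply(out, `[`, "", 3))
}

## classify one difference region. X owns the region, Y lacks it.
.classifyRegion <- function(rs, re, X, Y, strand) {
    memb <- function(t, p) any(t$starts <= p & p <= t$ends)
    fx <- memb(X, rs - 1L)   # left flank exonic in X (then shared with Y)
    gx <- memb(X, re + 1L)   # right flank exonic in X
    idx <- which(X$starts <= rs & X$ends >= re)
    n <- length(X$starts)
    Ys <- min(Y$starts); Ye <- max(Y$ends)
    if (fx && gx) return("IR")
    if (fx && !gx) {
        xCont <- idx < n                 # X splices on to the genomic right
        yCont <- any(Y$starts > rs - 1L) # Y has a later exon
        if (xCont && yCont)
            return(if (strand == "+") "A5" else "A3")
        return(if (strand == "+") "ATTS" else "ATSS")
    }
    if (gx && !fx) {
        xCont <- idx > 1L
        yCont <- any(Y$ends < re + 1L)
        if (xCont && yCont)
            return(if (strand == "+") "A3" else "A5")
        return(if (strand == "+") "ATSS" else "ATTS")
    }
    ## region is a complete exon of X
    internal <- idx > 1L && idx < n
    insideY <- rs > Ys && re < Ye
    if (internal && insideY) return("ES")
    side <- if (idx == 1L && idx == n) {
        if (rs > Ye) "right" else "left"
    } else if (idx == 1L) "left"
    else if (idx == n) "right"
    else if (re < Ys) "left" else "right"
    if (side == "left")
        return(if (strand == "+") "ATSS" else "ATTS")
    if (strand == "+") "ATTS" else "ATSS"
}

.sites <- function(t) {
    n <- length(t$starts)
    if (n < 2L) integer(0) else c(t$ends[-n], t$starts[-1L])
}

## core pair annotator on plain structures
.annotatePairPlain <- function(pa, pb, cdsA = NULL, cdsB = NULL) {
    if (pa$chrom != pb$chrom || pa$strand != pb$strand)
        stop("isoforms must share chromosome and strand: ",
             pa$id, " vs ", pb$id)
    if (pa$id == pb$id) stop("isoform pair must be two distinct isoforms")
    strand <- pa$strand
    reg <- .diffRegions(pa, pb)
    empty <- .emptyEvents()
    if (!nrow(reg)) {
        attr(empty, "comparable") <- TRUE
        return(empty)
    }
    types <- character(nrow(reg))
    for (i in seq_len(nrow(reg))) {
        X <- if (reg$owner[i] == "a") pa else pb
        Y <- if (reg$owner[i] == "a") pb else pa
        types[i] <- .classifyRegion(reg$start[i], reg$end[i], X, Y, strand)
    }
    ## MES merge: consecutive ES regions of opposite owners with no
    ## shared-exonic base between them. Membership is piecewise constant
    ## between breakpoints, so checking segment start points suffices.
    sharedBetween <- function(lo, hi) {
        if (hi < lo) return(FALSE)
        pts <- unique(c(lo, c(pa$starts, pb$starts)[
            c(pa$starts, pb$starts) > lo & c(pa$starts, pb$starts) <= hi]))
        any(vapply(pts, function(p)
            any(pa$starts <= p & p <= pa$ends) &&
            any(pb$starts <= p & p <= pb$ends), logical(1)))
    }
    rows <- list()
    used <- logical(nrow(reg))
    esIdx <- which(types == "ES")
    k <- 1L
    while (k < length(esIdx)) {
        i <- esIdx[k]; j <- esIdx[k + 1L]
        if (!used[i] && !used[j] && reg$owner[i] != reg$owner[j] &&
            !sharedBetween(reg$end[i] + 1L, reg$start[j] - 1L)) {
            rows[[length(rows) + 1L]] <- data.frame(
                event_type = "MES", region_start = reg$start[i],
                region_end = reg$end[j],
                regions = paste0(reg$start[i], "-", reg$end[i], ";",
                                 reg$start[j], "-", reg$end[j]),
                owner = reg$owner[i])
            used[i] <- TRUE; used[j] <- TRUE
            k <- k + 2L
        } else k <- k + 1L
    }
    for (i in seq_len(nrow(reg))) {
        if (used[i]) next
        rows[[length(rows) + 1L]] <- data.frame(
            event_type = types[i], region_start = reg$start[i],
            region_end = reg$end[i],
            regions = paste0(reg$start[i], "-", reg$end[i]),
            owner = reg$owner[i])
    }
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$region_start, ev$region_end), , drop = FALSE]
    ## incomparability: end-type differences with no shared splice site
    sharedSite <- length(intersect(.sites(pa), .sites(pb))) > 0L
    if (!sharedSite && any(ev$event_type %in% c("ATSS", "ATTS"))) {
        attr(empty, "comparable") <- FALSE
        return(empty)
    }
    incr <- rep(NA, nrow(ev))
    if (!is.null(cdsA) || !is.null(cdsB)) {
        hits <- function(cds, lo, hi) {
            !is.null(cds) && nrow(cds) > 0 &&
                any(cds$start <= hi & cds$end >= lo)
        }
        for (i in seq_len(nrow(ev))) {
            parts <- strsplit(ev$regions[i], ";", fixed = TRUE)[[1]]
            anyHit <- FALSE
            for (p in parts) {
                se <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
                if (hits(cdsA, se[1], se[2]) || hits(cdsB, se[1], se[2]))
                    anyHit <- TRUE
            }
            incr[i] <- anyHit
        }
    }
    out <- data.frame(gene_id = pa$gene, isoform_a = pa$id, isoform_b = pb$id,
                      event_type = ev$event_type,
                      region_start = ev$region_start,
                      region_end = ev$region_end,
                      regions = ev$regions, owner = ev$owner,
                      in_coding_region = incr, row.names = NULL)
    attr(out, "comparable") <- TRUE
    out
}

#' Annotate alternative-splicing events on an isoform pair
#'
#' Decomposes the difference between two exon chains (same chromosome and
#' strand) into maximal single-isoform regions and assigns each exactly one
#' of the seven event types; adjacent skipped-exon regions owned by
#' opposite isoforms with no shared exon between them are merged into a
#' single MES event. Identical exon chains produce zero events. When the
#' two isoforms share no splice site and the difference involves transcript
#' ends, the pair is reported incomparable (zero rows, attribute
#' `comparable = FALSE`) and is excluded from tallies.
#'
#' @param a,b Single-transcript [TranscriptSet]s sharing chromosome and
#'   strand.
#' @param cdsA,cdsB Optional data.frames of genomic CDS intervals (columns
#'   `start`, `end`); when supplied, each event gains an
#'   `in_coding_region` flag (TRUE when the region intersects either CDS).
#' @return data.frame with columns `gene_id`, `isoform_a`, `isoform_b`,
#'   `event_type`, `region_start`, `region_end`, `regions` (";"-joined
#'   intervals, two for MES), `owner` (`"a"`/`"b"`: which isoform contains
#'   the region) and `in_coding_region`; attribute `comparable`.
#' @export
annotatePair <- function(a, b, cdsA = NULL, cdsB = NULL) {
    .annotatePairPlain(.plainTx(a)[[1]], .plainTx(b)[[1]], cdsA, cdsB)
}

#' Annotate events for many isoform pairs at once
#'
#' Batch form of [annotatePair()]: the transcript set is decoded once and
#' each row of `pairs` is annotated.
#'
#' @param ts A [TranscriptSet] containing all referenced isoforms.
#' @param pairs data.frame with columns `isoform_a`, `isoform_b`.
#' @param cds Optional named list of CDS data.frames per isoform.
#' @param simplify Combine all pairs into one table (default). With
#'   `FALSE`, return a named list (`"a|b"`) of per-pair tables, each with
#'   its `comparable` attribute.
#' @return Combined event rows (incomparable pairs dropped and listed in
#'   the `incomparable_pairs` attribute), or the per-pair list.
#' @export
annotatePairs <- function(ts, pairs, cds = NULL, simplify = TRUE) {
    plain <- .plainTx(ts)
    if (!simplify) {
        out <- vector("list", nrow(pairs))
        for (i in seq_len(nrow(pairs))) {
            ia <- pairs$isoform_a[i]; ib <- pairs$isoform_b[i]
            out[[i]] <- .annotatePairPlain(
                plain[[ia]], plain[[ib]],
                cdsA = if (!is.null(cds)) cds[[ia]] else NULL,
                cdsB = if (!is.null(cds)) cds[[ib]] else NULL)
        }
        names(out) <- paste(pairs$isoform_a, pairs$isoform_b, sep = "|")
        return(out)
    }
    res <- list(); bad <- list()
    for (i in seq_len(nrow(pairs))) {
        ia <- pairs$isoform_a[i]; ib <- pairs$isoform_b[i]
        ev <- .annotatePairPlain(plain[[ia]], plain[[ib]],
                                 cdsA = if (!is.null(cds)) cds[[ia]] else NULL,
                                 cdsB = if (!is.null(cds)) cds[[ib]] else NULL)
        if (!attr(ev, "comparable"))
            bad[[length(bad) + 1L]] <- c(ia, ib)
        else if (nrow(ev)) res[[length(res) + 1L]] <- ev
    }
    out <- if (length(res)) do.call(rbind, res) else .emptyEvents()
    rownames(out) <- NULL
    attr(out, "incomparable_pairs") <- bad
    out
}

#' Annotate events for the isoform pairs of a locus
#'
#' @param locus A [TranscriptSet] with >= 2 transcripts of one gene.
#' @param pairs Optional data.frame with columns `isoform_a`, `isoform_b`
#'   (e.g. switch pairs); default: all unordered pairs.
#' @param cds Optional named list of CDS data.frames per transcript (from
#'   [predictOrfs()]), used for `in_coding_region`.
#' @return As [annotatePairs()].
#' @export
annotateLocus <- function(locus, pairs = NULL, cds = NULL) {
    ids <- transcriptIds(locus)
    if (length(ids) < 2L) stop("locus needs at least two isoforms")
    if (is.null(pairs)) {
        cmb <- combn(sort(ids), 2L)
        pairs <- data.frame(isoform_a = cmb[1, ], isoform_b = cmb[2, ])
    }
    annotatePairs(locus, pairs, cds = cds)
}

#' Distribution of event types, optionally split by bias direction
#'
#' @param events Event rows from [annotatePair()]/[annotateLocus()].
#' @param biasLabels Optional named character vector mapping isoform id to
#'   `"female"`/`"male"`/`"none"`; an event is attributed to the bias of
#'   the isoform that contains its region (the `owner`).
#' @return data.frame with `event_type`, `count`, `fraction` (summing to 1)
#'   and, when labels are given, `count_female`, `count_male`.
#' @export
eventTypeDistribution <- function(events, biasLabels = NULL) {
    if (!nrow(events))
        return(data.frame(event_type = character(0), count = integer(0),
                          fraction = numeric(0)))
    tab <- table(factor(events$event_type, levels = .EVENT_TYPES))
    tab <- tab[tab > 0]
    out <- data.frame(event_type = names(tab), count = as.integer(tab),
                      fraction = as.integer(tab) / sum(tab))
    if (!is.null(biasLabels)) {
        ownerId <- ifelse(events$owner == "a", events$isoform_a,
                          events$isoform_b)
        bias <- biasLabels[ownerId]
        out$count_female <- vapply(out$event_type, function(ty)
            sum(events$event_type == ty & bias == "female", na.rm = TRUE),
            integer(1))
        out$count_male <- vapply(out$event_type, function(ty)
            sum(events$event_type == ty & bias == "male", na.rm = TRUE),
            integer(1))
    }
    rownames(out) <- NULL
    out
}

## per-base oracle on plain structures (coordinates must be modest)
.bruteForcePairPlain <- function(pa, pb) {
    if (pa$chrom != pb$chrom || pa$strand != pb$strand)
        stop("isoforms must share chromosome and strand")
    M <- max(pa$ends, pb$ends) + 2L
    mirror <- pa$strand == "-"
    if (mirror) {
        flip <- function(t) {
            s <- M - rev(t$ends); e <- M - rev(t$starts)
            t$starts <- s; t$ends <- e; t$strand <- "+"
            t
        }
        qa <- flip(pa); qb <- flip(pb)
    } else {
        qa <- pa; qb <- pb
    }
    L <- max(qa$ends, qb$ends) + 1L
    vec <- function(t) {
        v <- logical(L)
        for (i in seq_along(t$starts)) v[t$starts[i]:t$ends[i]] <- TRUE
        v
    }
    va <- vec(qa); vb <- vec(qb)
    classify1 <- function(vx, vy, rs, re) {
        at <- function(v, p) p >= 1L && p <= L && v[p]
        fx <- at(vx, rs - 1L); gx <- at(vx, re + 1L)
        if (fx && gx) return("IR")
        whichX <- which(vx)
        runStart <- rs
        while (runStart > 1L && vx[runStart - 1L]) runStart <- runStart - 1L
        runEnd <- re
        while (runEnd < L && vx[runEnd + 1L]) runEnd <- runEnd + 1L
        isFirst <- !any(whichX < runStart)
        isLast <- !any(whichX > runEnd)
        whichY <- which(vy)
        Ys <- min(whichY); Ye <- max(whichY)
        if (fx && !gx) {
            if (!isLast && any(whichY > rs - 1L)) return("A5")
            return("ATTS")
        }
        if (gx && !fx) {
            if (!isFirst && any(whichY < re + 1L)) return("A3")
            return("ATSS")
        }
        internal <- !isFirst && !isLast
        insideY <- rs > Ys && re < Ye
        if (internal && insideY) return("ES")
        side <- if (isFirst && isLast) {
            if (rs > Ye) "right" else "left"
        } else if (isFirst) "left"
        else if (isLast) "right"
        else if (re < Ys) "left" else "right"
        if (side == "left") "ATSS" else "ATTS"
    }
    runs <- function(mask) {
        d <- diff(c(FALSE, mask, FALSE))
        data.frame(start = which(d == 1L), end = which(d == -1L) - 1L)
    }
    ra <- runs(va & !vb); rb <- runs(vb & !va)
    reg <- rbind(
        if (nrow(ra)) data.frame(ra, owner = "a") else NULL,
        if (nrow(rb)) data.frame(rb, owner = "b") else NULL)
    empty <- data.frame(event_type = character(0), region_start = integer(0),
                        region_end = integer(0), owner = character(0))
    if (is.null(reg) || !nrow(reg)) {
        attr(empty, "comparable") <- TRUE
        return(empty)
    }
    reg <- reg[order(reg$start), , drop = FALSE]
    types <- vapply(seq_len(nrow(reg)), function(i) {
        if (reg$owner[i] == "a") classify1(va, vb, reg$start[i], reg$end[i])
        else classify1(vb, va, reg$start[i], reg$end[i])
    }, character(1))
    sharedGap <- function(lo, hi) {   # any both-exonic base, mirrored coords
        if (hi < lo) return(FALSE)
        any(va[lo:hi] & vb[lo:hi])
    }
    if (mirror) {
        ## mirroring plus the strand flip is the reverse-complement view:
        ## event types are invariant; map regions back to the original
        ## coordinates before the (genomic-order) MES merge
        ns <- M - reg$end; ne <- M - reg$start
        reg$start <- ns; reg$end <- ne
        o <- order(reg$start)
        reg <- reg[o, , drop = FALSE]
        types <- types[o]
        sharedGap <- function(lo, hi) {
            if (hi < lo) return(FALSE)
            ml <- M - hi; mh <- M - lo
            any(va[ml:mh] & vb[ml:mh])
        }
    }
    used <- logical(nrow(reg))
    rows <- list()
    esIdx <- which(types == "ES")
    k <- 1L
    while (k < length(esIdx)) {
        i <- esIdx[k]; j <- esIdx[k + 1L]
        if (!used[i] && !used[j] && reg$owner[i] != reg$owner[j] &&
            !sharedGap(reg$end[i] + 1L, reg$start[j] - 1L)) {
            rows[[length(rows) + 1L]] <- data.frame(
                event_type = "MES", region_start = reg$start[i],
                region_end = reg$end[j], owner = reg$owner[i])
            used[c(i, j)] <- TRUE
            k <- k + 2L
        } else k <- k + 1L
    }
    for (i in seq_len(nrow(reg))) {
        if (used[i]) next
        rows[[length(rows) + 1L]] <- data.frame(
            event_type = types[i], region_start = reg$start[i],
            region_end = reg$end[i], owner = reg$owner[i])
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$region_start, out$region_end), , drop = FALSE]
    sharedSite <- length(intersect(.sites(pa), .sites(pb))) > 0L
    if (!sharedSite && any(out$event_type %in% c("ATSS", "ATTS"))) {
        attr(empty, "comparable") <- FALSE
        return(empty)
    }
    rownames(out) <- NULL
    attr(out, "comparable") <- TRUE
    out
}

#' Per-base reference implementation of the pair annotator
#'
#' Independent oracle used for validation: exonic membership is expanded
#' into per-base logical vectors, minus-strand pairs are handled by
#' mirroring coordinates onto the plus strand (so strand covariance is
#' structural rather than re-coded), and the region rule table is applied
#' on the vectors. Coordinates must be modest (vectors are allocated up to
#' the locus end).
#'
#' @inheritParams annotatePair
#' @return data.frame with columns `event_type`, `region_start`,
#'   `region_end`, `owner`, sorted by region; attribute `comparable`.
#' @export
bruteForcePairEvents <- function(a, b) {
    .bruteForcePairPlain(.plainTx(a)[[1]], .plainTx(b)[[1]])
}

#' Batch form of [bruteForcePairEvents()]
#'
#' @inheritParams annotatePairs
#' @return Named list of per-pair oracle tables (with `comparable`
#'   attributes), names `"a|b"`.
#' @export
bruteForcePairs <- function(ts, pairs) {
    plain <- .plainTx(ts)
    out <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        out[[i]] <- .bruteForcePairPlain(plain[[pairs$isoform_a[i]]],
                                         plain[[pairs$isoform_b[i]]])
    }
    names(out) <- paste(pairs$isoform_a, pairs$isoform_b, sep = "|")
    out
}
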