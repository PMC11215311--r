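## Structural classification of query transcripts against a reference
## annotation, artifact filtering on junction motifs/coverage, and
## reconstruction status against short-read assembled transcripts.

.CATEGORIES <- c("FSM", "ISM", "NIC", "NNC", "Antisense", "Genic",
                 "Intergenic", "Fusion")

## genomic-order junction keys "end_i:start_{i+1}"
.chainKeys <- function(t) {
    n <- length(t$starts)
    if (n < 2L) return(character(0))
    paste(t$ends[-n], t$starts[-1L], sep = ":")
}

## is `sub` a consecutive (contiguous) proper sub-chain of `full`?
.isConsecSub <- function(sub, full) {
    ns <- length(sub); nf <- length(full)
    if (ns < 1L || ns >= nf) return(FALSE)
    for (off in 0:(nf - ns)) {
        if (all(sub == full[(off + 1L):(off + ns)])) return(TRUE)
    }
    FALSE
}

## reference index keyed for the classifier
.refIndex <- function(reference) {
    plain <- .plainTx(reference)
    genes <- vapply(plain, `[[`, character(1), "gene")
    byGene <- split(seq_along(plain), genes)
    loci <- lapply(byGene, function(ix) {
        txs <- plain[ix]
        chains <- lapply(txs, .chainKeys)
        leftSites <- unique(unlist(lapply(txs, function(t)
            t$ends[-length(t$ends)]), use.names = FALSE))
        rightSites <- unique(unlist(lapply(txs, function(t)
            t$starts[-1L]), use.names = FALSE))
        mono <- txs[vapply(txs, function(t) length(t$starts) == 1L, logical(1))]
        list(chrom = txs[[1]]$chrom, strand = txs[[1]]$strand,
             span = c(min(vapply(txs, function(t) min(t$starts), numeric(1))),
                      max(vapply(txs, function(t) max(t$ends), numeric(1)))),
             tx = txs, chains = chains,
             junctions = unique(unlist(chains, use.names = FALSE)),
             leftSites = leftSites, rightSites = rightSites,
             mono = mono)
    })
    list(plain = plain, loci = loci)
}

## exon-level overlap hit lists between a query set and reference loci
.lociHits <- function(qplain, idx, opposite = FALSE) {
    locNames <- names(idx$loci)
    if (!length(locNames) || !length(qplain))
        return(rep(list(character(0)), length(qplain)))
    refEx <- do.call(rbind, lapply(seq_along(idx$loci), function(i) {
        l <- idx$loci[[i]]
        do.call(rbind, lapply(l$tx, function(t)
            data.frame(chrom = t$chrom, start = t$starts, end = t$ends,
                       strand = t$strand, locus = i)))
    }))
    qEx <- do.call(rbind, lapply(seq_along(qplain), function(i) {
        t <- qplain[[i]]
        s <- t$strand
        if (opposite) s <- if (s == "+") "-" else "+"
        data.frame(chrom = t$chrom, start = t$starts, end = t$ends,
                   strand = s, q = i)
    }))
    grR <- GRanges(refEx$chrom, IRanges(refEx$start, refEx$end), refEx$strand)
    grQ <- GRanges(qEx$chrom, IRanges(qEx$start, qEx$end), qEx$strand)
    h <- findOverlaps(grQ, grR)
    res <- rep(list(integer(0)), length(qplain))
    if (length(h)) {
        qi <- qEx$q[S4Vectors::queryHits(h)]
        li <- refEx$locus[S4Vectors::subjectHits(h)]
        sp <- split(li, qi)
        for (k in names(sp)) res[[as.integer(k)]] <- sort(unique(sp[[k]]))
    }
    lapply(res, function(i) locNames[i])
}

## pick the preferred reference transcript id among candidates:
## longest spliced length, then lexicographic id
.pickRef <- function(cands, lens) {
    if (!length(cands)) return(NA_character_)
    o <- order(-lens[cands], cands)
    cands[o[1]]
}

#' Classify transcripts against a reference annotation
#'
#' Assigns each query transcript exactly one structural category relative
#' to the reference annotation, by precedence: `Fusion` (same-strand exonic
#' overlap with two or more reference loci, multi-exon queries), `FSM`
#' (junction chain identical to a reference transcript; terminal exon ends
#' are ignored), `ISM` (proper consecutive sub-chain of a reference chain),
#' `NIC` (every donor and acceptor annotated at the locus, novel
#' combination), `NNC` (at least one unannotated splice site), `Antisense`
#' (exonic overlap only on the opposite strand), `Genic` (overlap with the
#' gene body that fits none of the above, including mono-exon queries not
#' contained in a reference mono-exon transcript), `Intergenic` (no overlap
#' with any reference gene). Mono-exon queries are `FSM` when contained
#' within a reference mono-exon transcript's exon.
#'
#' @param query,reference [TranscriptSet] objects on the same genome.
#' @return data.frame with columns `transcript_id`, `category`,
#'   `matched_reference_id`, `novel_junction_count`.
#' @seealso [bruteForceClassify()] for the enumeration-based reference
#'   implementation used in validation.
#' @export
classifyTranscripts <- function(query, reference) {
    qplain <- .plainTx(query)
    if (!length(reference)) {
        warning("empty reference annotation: all queries Intergenic")
        return(data.frame(
            transcript_id = names(qplain),
            category = rep("Intergenic", length(qplain)),
            matched_reference_id = NA_character_,
            novel_junction_count = vapply(qplain, function(t)
                max(length(t$starts) - 1L, 0L), integer(1)),
            row.names = NULL))
    }
    idx <- .refIndex(reference)
    lens <- splicedLength(reference)
    hitSame <- .lociHits(qplain, idx)                 # same-strand exonic
    hitAnti <- .lociHits(qplain, idx, opposite = TRUE)

    locSpan <- do.call(rbind, lapply(names(idx$loci), function(nm) {
        l <- idx$loci[[nm]]
        data.frame(chrom = l$chrom, start = l$span[1], end = l$span[2],
                   strand = l$strand, locus = nm)
    }))
    grSpan <- GRanges(locSpan$chrom, IRanges(locSpan$start, locSpan$end),
                      locSpan$strand)
    qSpan <- GRanges(vapply(qplain, `[[`, character(1), "chrom"),
                     IRanges(vapply(qplain, function(t) min(t$starts), numeric(1)),
                             vapply(qplain, function(t) max(t$ends), numeric(1))),
                     vapply(qplain, `[[`, character(1), "strand"))
    spanHits <- findOverlaps(qSpan, grSpan)
    spanList <- rep(list(character(0)), length(qplain))
    if (length(spanHits)) {
        sp <- split(locSpan$locus[S4Vectors::subjectHits(spanHits)],
                    S4Vectors::queryHits(spanHits))
        for (k in names(sp)) spanList[[as.integer(k)]] <- unique(sp[[k]])
    }

    n <- length(qplain)
    category <- character(n); matched <- rep(NA_character_, n)
    novel <- integer(n)
    for (i in seq_len(n)) {
        t <- qplain[[i]]
        L <- hitSame[[i]]
        qkeys <- .chainKeys(t)
        refJunc <- unique(unlist(lapply(idx$loci[L], `[[`, "junctions"),
                                 use.names = FALSE))
        novel[i] <- sum(!(qkeys %in% refJunc))
        multi <- length(t$starts) > 1L
        if (multi && length(L) >= 2L) {
            category[i] <- "Fusion"
            next
        }
        if (multi && length(L) >= 1L) {
            chains <- unlist(lapply(L, function(nm) idx$loci[[nm]]$chains),
                             recursive = FALSE)
            eq <- names(chains)[vapply(chains, function(ch)
                length(ch) == length(qkeys) && all(ch == qkeys), logical(1))]
            if (length(eq)) {
                category[i] <- "FSM"; matched[i] <- .pickRef(eq, lens)
                next
            }
            sub <- names(chains)[vapply(chains, function(ch)
                .isConsecSub(qkeys, ch), logical(1))]
            if (length(sub)) {
                category[i] <- "ISM"; matched[i] <- .pickRef(sub, lens)
                next
            }
            lefts <- unique(unlist(lapply(idx$loci[L], `[[`, "leftSites")))
            rights <- unique(unlist(lapply(idx$loci[L], `[[`, "rightSites")))
            nq <- length(t$starts)
            if (all(t$ends[-nq] %in% lefts) && all(t$starts[-1L] %in% rights)) {
                category[i] <- "NIC"
            } else {
                category[i] <- "NNC"
            }
            next
        }
        if (!multi && length(L) >= 1L) {
            # mono-exon: FSM when contained in a reference mono-exon exon
            cont <- character(0)
            for (nm in L) {
                for (m in idx$loci[[nm]]$mono) {
                    if (m$starts[1] <= t$starts[1] && m$ends[1] >= t$ends[1])
                        cont <- c(cont, m$id)
                }
            }
            if (length(cont)) {
                category[i] <- "FSM"; matched[i] <- .pickRef(cont, lens)
            } else {
                category[i] <- "Genic"
            }
            next
        }
        # no same-strand exonic overlap
        if (length(hitAnti[[i]])) {
            category[i] <- "Antisense"
        } else if (length(spanList[[i]])) {
            category[i] <- "Genic"
        } else {
            category[i] <- "Intergenic"
        }
    }
    data.frame(transcript_id = names(qplain), category = category,
               matched_reference_id = matched,
               novel_junction_count = novel, row.names = NULL)
}

#' Brute-force reference classifier
#'
#' Independent implementation of the structural classification used for
#' validation: it enumerates every reference chain and every consecutive
#' sub-chain as delimited strings, recomputes overlap and annotated-site
#' sets by direct looping, and applies the same category precedence. Slower
#' but transparently exhaustive.
#'
#' @inheritParams classifyTranscripts
#' @return Same shape as [classifyTranscripts()] (without
#'   `matched_reference_id` tie-break guarantees; the category and counts
#'   are the comparable part).
#' @export
bruteForceClassify <- function(query, reference) {
    qplain <- .plainTx(query)
    rplain <- .plainTx(reference)
    if (!length(rplain)) {
        return(data.frame(
            transcript_id = names(qplain),
            category = rep("Intergenic", length(qplain)),
            matched_reference_id = NA_character_,
            novel_junction_count = vapply(qplain, function(t)
                max(length(t$starts) - 1L, 0L), integer(1)),
            row.names = NULL))
    }
    ovl <- function(s1, e1, s2, e2) {
        any(outer(s1, e2, "<=") & outer(e1, s2, ">="))
    }
    chainStr <- function(t) {
        n <- length(t$starts)
        if (n < 2L) return("")
        paste0("_", paste(t$ends[-n], t$starts[-1L], sep = "x",
                          collapse = "_"), "_")
    }
    genes <- vapply(rplain, `[[`, character(1), "gene")
    out <- data.frame(transcript_id = names(qplain),
                      category = NA_character_,
                      matched_reference_id = NA_character_,
                      novel_junction_count = 0L)
    for (i in seq_along(qplain)) {
        q <- qplain[[i]]
        sameEx <- vapply(rplain, function(r)
            r$chrom == q$chrom && r$strand == q$strand &&
            ovl(q$starts, q$ends, r$starts, r$ends), logical(1))
        antiEx <- vapply(rplain, function(r)
            r$chrom == q$chrom && r$strand != q$strand &&
            ovl(q$starts, q$ends, r$starts, r$ends), logical(1))
        sameLoci <- unique(genes[sameEx])
        qs <- chainStr(q)
        nq <- length(q$starts)
        # novel junction count against loci hit (or none)
        refJ <- unique(unlist(lapply(rplain[genes %in% sameLoci], function(r) {
            n <- length(r$starts)
            if (n < 2L) character(0)
            else paste(r$ends[-n], r$starts[-1L], sep = "x")
        })))
        qJ <- if (nq < 2L) character(0) else
            paste(q$ends[-nq], q$starts[-1L], sep = "x")
        out$novel_junction_count[i] <- sum(!(qJ %in% refJ))
        if (nq > 1L && length(sameLoci) >= 2L) {
            out$category[i] <- "Fusion"; next
        }
        if (nq > 1L && length(sameLoci) == 1L) {
            cand <- rplain[genes == sameLoci & vapply(rplain, function(r)
                r$chrom == q$chrom && r$strand == q$strand, logical(1))]
            full <- vapply(cand, function(r) identical(chainStr(r), qs),
                           logical(1))
            if (any(full)) {
                out$category[i] <- "FSM"
                out$matched_reference_id[i] <- cand[[which(full)[1]]]$id
                next
            }
            subm <- vapply(cand, function(r) {
                rs <- chainStr(r)
                nchar(rs) > nchar(qs) && grepl(qs, rs, fixed = TRUE)
            }, logical(1))
            if (any(subm)) {
                out$category[i] <- "ISM"
                out$matched_reference_id[i] <- cand[[which(subm)[1]]]$id
                next
            }
            lefts <- unlist(lapply(cand, function(r)
                r$ends[-length(r$ends)]))
            rights <- unlist(lapply(cand, function(r) r$starts[-1L]))
            if (all(q$ends[-nq] %in% lefts) && all(q$starts[-1L] %in% rights))
                out$category[i] <- "NIC"
            else
                out$category[i] <- "NNC"
            next
        }
        if (nq == 1L && length(sameLoci) >= 1L) {
            contained <- FALSE
            for (r in rplain[genes %in% sameLoci]) {
                if (r$strand == q$strand && r$chrom == q$chrom &&
                    length(r$starts) == 1L &&
                    r$starts[1] <= q$starts[1] && r$ends[1] >= q$ends[1]) {
                    contained <- TRUE
                    out$matched_reference_id[i] <- r$id
                    break
                }
            }
            out$category[i] <- if (contained) "FSM" else "Genic"
            next
        }
        if (any(antiEx)) { out$category[i] <- "Antisense"; next }
        spanHit <- any(vapply(unique(genes), function(g) {
            rs <- rplain[genes == g]
            if (rs[[1]]$chrom != q$chrom || rs[[1]]$strand != q$strand)
                return(FALSE)
            lo <- min(vapply(rs, function(r) min(r$starts), numeric(1)))
            hi <- max(vapply(rs, function(r) max(r$ends), numeric(1)))
            min(q$starts) <= hi && max(q$ends) >= lo
        }, logical(1)))
        out$category[i] <- if (spanHit) "Genic" else "Intergenic"
    }
    out
}

#' Junction support table: motifs and short-read coverage
#'
#' For every junction of every query transcript, reports the 4-letter
#' splice motif (donor dinucleotide + acceptor dinucleotide in transcript
#' orientation) read from the genome, the short-read coverage looked up in
#' `juncCov`, and whether the junction is novel (absent from the reference
#' junction set on the same chromosome and strand).
#'
#' @param query A [TranscriptSet].
#' @param reference A [TranscriptSet] (the annotation).
#' @param genome `DNAStringSet` named by chromosome.
#' @param juncCov data.frame with columns `chrom`, `strand`, `donor`,
#'   `acceptor` (transcript-orientation positions as in [junctionChain()])
#'   and `coverage`.
#' @return data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `donor`, `acceptor`, `motif`, `coverage`, `is_novel`.
#' @export
junctionSupport <- function(query, reference, genome, juncCov) {
    chains <- junctionChain(query)
    ch <- txChrom(query); sd <- txStrand(query)
    refChains <- junctionChain(reference)
    refCh <- txChrom(reference); refSd <- txStrand(reference)
    refKey <- unlist(lapply(seq_along(refChains), function(i) {
        j <- refChains[[i]]
        if (!nrow(j)) return(character(0))
        paste(refCh[i], refSd[i], j$donor, j$acceptor)
    }), use.names = FALSE)
    rows <- lapply(seq_along(chains), function(i) {
        j <- chains[[i]]
        if (!nrow(j)) return(NULL)
        data.frame(transcript_id = names(chains)[i], chrom = unname(ch[i]),
                   strand = unname(sd[i]), donor = j$donor,
                   acceptor = j$acceptor)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        return(data.frame(transcript_id = character(0), chrom = character(0),
                          strand = character(0), donor = integer(0),
                          acceptor = integer(0), motif = character(0),
                          coverage = integer(0), is_novel = logical(0)))
    motif <- character(nrow(tab))
    for (k in seq_len(nrow(tab))) {
        chr <- genome[[tab$chrom[k]]]
        if (is.null(chr)) stop("chromosome not in genome: ", tab$chrom[k])
        if (tab$strand[k] == "+") {
            dn <- as.character(subseq(chr, tab$donor[k] + 1L, tab$donor[k] + 2L))
            ac <- as.character(subseq(chr, tab$acceptor[k] - 2L,
                                      tab$acceptor[k] - 1L))
        } else {
            dn <- as.character(reverseComplement(
                subseq(chr, tab$donor[k] - 2L, tab$donor[k] - 1L)))
            ac <- as.character(reverseComplement(
                subseq(chr, tab$acceptor[k] + 1L, tab$acceptor[k] + 2L)))
        }
        motif[k] <- paste0(dn, ac)
    }
    tab$motif <- motif
    key <- paste(tab$chrom, tab$strand, tab$donor, tab$acceptor)
    covKey <- paste(juncCov$chrom, juncCov$strand, juncCov$donor,
                    juncCov$acceptor)
    tab$coverage <- juncCov$coverage[match(key, covKey)]
    tab$is_novel <- !(key %in% refKey)
    rownames(tab) <- NULL
    tab
}

#' Filter artifact transcripts by splice motif and junction coverage
#'
#' Transcripts in a novel category (NIC, NNC, Genic, Intergenic, Antisense,
#' Fusion) are retained only when every junction motif is canonical
#' (GT-AG, GC-AG or AT-AC in transcript orientation) and every novel
#' junction has short-read coverage of at least `minCov`. FSM and ISM
#' transcripts are always retained.
#'
#' @param calls Output of [classifyTranscripts()].
#' @param support Output of [junctionSupport()].
#' @param minCov Minimum short-read coverage for novel junctions
#'   (default 3).
#' @return `calls` with an added logical column `retained`.
#' @export
filterArtifacts <- function(calls, support, minCov = 3L) {
    canonical <- c("GTAG", "GCAG", "ATAC")
    novelCat <- c("NIC", "NNC", "Genic", "Intergenic", "Antisense", "Fusion")
    retained <- rep(TRUE, nrow(calls))
    for (i in seq_len(nrow(calls))) {
        if (!(calls$category[i] %in% novelCat)) next
        s <- support[support$transcript_id == calls$transcript_id[i], ,
                     drop = FALSE]
        if (!nrow(s)) next  # mono-exon novel transcript: nothing to check
        if (!all(s$motif %in% canonical)) {
            retained[i] <- FALSE
            next
        }
        nv <- s[s$is_novel, , drop = FALSE]
        if (anyNA(nv$coverage))
            stop("missing junction support record for ",
                 calls$transcript_id[i], " junction ",
                 nv$donor[which(is.na(nv$coverage))[1]], "-",
                 nv$acceptor[which(is.na(nv$coverage))[1]])
        if (nrow(nv) && any(nv$coverage < minCov)) retained[i] <- FALSE
    }
    calls$retained <- retained
    calls
}

#' Reconstruction status of long-read isoforms from short-read transcripts
#'
#' For each isoform, `full` when some candidate short-read transcript has
#' an identical junction chain and exon count; `partial` when some
#' multi-exon candidate has fewer exons and its junction chain is a
#' consecutive sub-chain of the isoform's (every junction identical);
#' otherwise `fail`. Candidates are short-read transcripts with same-strand
#' exonic overlap. Mono-exon isoforms are `full` when an overlapping
#' mono-exon candidate exists.
#'
#' @param iso A [TranscriptSet] of long-read isoforms.
#' @param rnaseq A [TranscriptSet] of assembled short-read transcripts.
#' @return data.frame with columns `transcript_id`, `status`,
#'   `supporting_rnaseq_id`.
#' @export
reconstructionStatus <- function(iso, rnaseq) {
    ip <- .plainTx(iso); rp <- .plainTx(rnaseq)
    ovl <- function(a, b) {
        a$chrom == b$chrom && a$strand == b$strand &&
            any(outer(a$starts, b$ends, "<=") & outer(a$ends, b$starts, ">="))
    }
    status <- character(length(ip)); supp <- rep(NA_character_, length(ip))
    for (i in seq_along(ip)) {
        t <- ip[[i]]
        tk <- .chainKeys(t)
        cand <- Filter(function(r) ovl(t, r), rp)
        cand <- cand[order(vapply(cand, `[[`, character(1), "id"))]
        st <- "fail"; sid <- NA_character_
        for (r in cand) {
            rk <- .chainKeys(r)
            if (length(r$starts) == length(t$starts) &&
                length(rk) == length(tk) && all(rk == tk)) {
                st <- "full"; sid <- r$id; break
            }
        }
        if (st == "fail" && length(tk)) {
            for (r in cand) {
                rk <- .chainKeys(r)
                if (length(r$starts) < length(t$starts) && length(rk) >= 1L &&
                    .isConsecSub(rk, tk)) {
                    st <- "partial"; sid <- r$id; break
                }
            }
        }
        status[i] <- st; supp[i] <- sid
    }
    data.frame(transcript_id = names(ip), status = status,
               supporting_rnaseq_id = supp, row.names = NULL)
}

#' Tally of structural categories
#'
#' @param calls Output of [classifyTranscripts()].
#' @return data.frame with columns `category`, `count`, `fraction`, sorted
#'   by descending count (empty for empty input); fractions sum to 1.
#' @export
categoryTally <- function(calls) {
    if (!nrow(calls))
        return(data.frame(category = character(0), count = integer(0),
                          fraction = numeric(0)))
    tab <- table(factor(calls$category, levels = .CATEGORIES))
    tab <- tab[tab > 0]
    out <- data.frame(category = names(tab), count = as.integer(tab),
                      fraction = as.numeric(tab) / sum(tab))
    out <- out[order(-out$count, out$category), ]
    rownames(out) <- NULL
    out
}
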