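## Deterministic synthetic-data generator with recorded ground truth for
## every downstream stage: genome, reference/long-read/short-read transcript
## models, junction coverage, negative-binomial counts with planted
## sex-biased isoform-usage shifts, and upstream regions with planted motif
## instances. Structural truths (categories, event types, reconstruction
## status) are constructed to be exactly recoverable; statistical noise is
## confined to counts and background sequence.

.SLOT <- 30000L          # genomic territory per gene
.UPSTREAM_PAD <- 6500L   # promoter space upstream of every TSS

#' Simulation configuration
#'
#' Defaults emulate the antennal study conditions: 59% single-isoform loci
#' (so ~41% multi-isoform), ATSS/ATTS shares of 31%/33% among event types,
#' reconstruction mix 24.8/29.3/45.9%, 10% of multi-isoform genes with
#' planted switches at |dIF| = 0.4, 6 replicates per sex, NB dispersion
#' 0.05 (Var = mu + phi mu^2).
#'
#' @param seed Mandatory integer seed; every component derives its stream
#'   from it.
#' @param nGenes Number of gene loci.
#' @param genesPerChrom Loci per simulated chromosome.
#' @param isoformsPerGene Named probabilities over isoform counts
#'   ("1".."4").
#' @param eventMix Named fractions over the seven AS types used when
#'   constructing extra isoforms.
#' @param switchFraction Fraction of multi-isoform genes given a planted
#'   usage switch.
#' @param plantedDIF Planted isoform-fraction difference (female - male)
#'   of the female-preferred isoform.
#' @param nReplicates Samples per sex.
#' @param dispersion NB dispersion phi.
#' @param librarySize Expected total counts per sample.
#' @param reconstructionMix Named fractions full/partial/fail for the
#'   short-read transcript set.
#' @param novelMix Named fractions over constructed novel-category
#'   transcripts (ISM/NIC/NNC/Antisense/Genic/Intergenic/Fusion).
#' @param novelPerGene Expected number of extra novel transcripts per gene.
#' @param motifPlantRate Per-gene probability of implanting the motif
#'   consensus upstream of the TSS.
#' @param motifWidth Width of the simulated position frequency matrix.
#' @param covRange Junction coverage range (uniform integer draw).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed,
                             nGenes = 200L,
                             genesPerChrom = 50L,
                             isoformsPerGene = c("1" = 0.59, "2" = 0.15,
                                                 "3" = 0.143, "4" = 0.117),
                             eventMix = c(ATSS = 0.31, ATTS = 0.33,
                                          A5 = 0.09, A3 = 0.09, ES = 0.10,
                                          IR = 0.05, MES = 0.03),
                             switchFraction = 0.1,
                             plantedDIF = 0.4,
                             nReplicates = 6L,
                             dispersion = 0.05,
                             librarySize = 1e6,
                             reconstructionMix = c(full = 0.248,
                                                   partial = 0.293,
                                                   fail = 0.459),
                             novelMix = c(ISM = 0.20, NIC = 0.25, NNC = 0.30,
                                          Antisense = 0.05, Genic = 0.05,
                                          Intergenic = 0.10, Fusion = 0.05),
                             novelPerGene = 0.3,
                             motifPlantRate = 0.8,
                             motifWidth = 12L,
                             covRange = c(5L, 60L)) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(nGenes >= 1L, abs(sum(isoformsPerGene) - 1) < 1e-8,
              abs(sum(eventMix) - 1) < 1e-8,
              abs(sum(reconstructionMix) - 1) < 1e-8,
              abs(sum(novelMix) - 1) < 1e-8,
              switchFraction >= 0, switchFraction <= 1,
              plantedDIF >= 0, plantedDIF <= 0.9,
              nReplicates >= 2L, dispersion >= 0, librarySize > 0,
              motifPlantRate >= 0, motifPlantRate <= 1)
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                genesPerChrom = as.integer(genesPerChrom),
                isoformsPerGene = isoformsPerGene, eventMix = eventMix,
                switchFraction = switchFraction, plantedDIF = plantedDIF,
                nReplicates = as.integer(nReplicates),
                dispersion = dispersion, librarySize = librarySize,
                reconstructionMix = reconstructionMix, novelMix = novelMix,
                novelPerGene = novelPerGene,
                motifPlantRate = motifPlantRate,
                motifWidth = as.integer(motifWidth), covRange = covRange)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate a genome
#'
#' Uniform i.i.d. ACGT chromosomes sized to hold `nGenes` in fixed 30 kb
#' territories (>= 10 kb spacing between gene bodies); deterministic given
#' the seed.
#'
#' @param cfg A [simulationConfig()].
#' @return `DNAStringSet` named `chr1`, `chr2`, ...
#' @export
simulateGenome <- function(cfg) {
    set.seed(cfg$seed + 11L)
    nChrom <- ceiling(cfg$nGenes / cfg$genesPerChrom)
    perChrom <- pmin(cfg$genesPerChrom,
                     cfg$nGenes - (seq_len(nChrom) - 1L) * cfg$genesPerChrom)
    seqs <- vapply(perChrom, function(k) {
        paste(sample(c("A", "C", "G", "T"), k * .SLOT + 5000L,
                     replace = TRUE), collapse = "")
    }, character(1))
    g <- DNAStringSet(seqs)
    names(g) <- paste0("chr", seq_len(nChrom))
    g
}

## structure of one base transcript within its slot
.baseModel <- function(slotStart, strand) {
    nEx <- sample(4:7, 1L)
    exLens <- sample(150:300, nEx, replace = TRUE)
    inLens <- sample(500:1200, nEx - 1L, replace = TRUE)
    bodyStart <- slotStart + if (strand == "+") .UPSTREAM_PAD else 2000L
    starts <- integer(nEx); ends <- integer(nEx)
    pos <- bodyStart + 1L
    for (j in seq_len(nEx)) {
        starts[j] <- pos
        ends[j] <- pos + exLens[j] - 1L
        pos <- ends[j] + if (j < nEx) inLens[j] + 1L else 0L
    }
    list(starts = starts, ends = ends)
}

## apply one AS edit (transcript orientation) to a base structure; returns
## list(starts, ends) or NULL when infeasible
.applyEdit <- function(base, strand, type) {
    s <- base$starts; e <- base$ends; n <- length(s)
    delta <- sample(60:90, 1L)
    first <- if (strand == "+") 1L else n     # first exon, transcript order
    last <- if (strand == "+") n else 1L
    switch(type,
        ATSS = {
            if (strand == "+") s[1] <- s[1] + delta else e[n] <- e[n] - delta
            list(starts = s, ends = e)
        },
        ATTS = {
            if (strand == "+") e[n] <- e[n] - delta else s[1] <- s[1] + delta
            list(starts = s, ends = e)
        },
        ES = {
            j <- sample(2:(n - 1L), 1L)
            list(starts = s[-j], ends = e[-j])
        },
        IR = {
            if (n < 4L) return(NULL)
            j <- sample(2:(n - 2L), 1L)  # retain intron j (internal)
            list(starts = s[-(j + 1L)], ends = e[-j])
        },
        A5 = {
            j <- sample(2:(n - 1L), 1L)
            d2 <- sample(30:90, 1L)
            if (strand == "+") e[j] <- e[j] + d2 else s[j] <- s[j] - d2
            list(starts = s, ends = e)
        },
        A3 = {
            j <- sample(2:(n - 1L), 1L)
            d2 <- sample(30:90, 1L)
            if (strand == "+") s[j] <- s[j] - d2 else e[j] <- e[j] + d2
            list(starts = s, ends = e)
        },
        MES = {
            j <- sample(2:(n - 1L), 1L)
            intLo <- e[j] + 1L; intHi <- s[j + 1L] - 1L
            if (intHi - intLo + 1L < 320L) return(NULL)
            cs <- intLo + 100L; ce <- cs + 119L
            s2 <- sort(c(s[-j], cs)); e2 <- sort(c(e[-j], ce))
            list(starts = s2, ends = e2)
        },
        stop("unknown edit type ", type))
}

.expectedCategory <- c(ATSS = "FSM", ATTS = "FSM", ES = "NIC", IR = "NIC",
                       A5 = "NNC", A3 = "NNC", MES = "NNC")

#' Simulate reference/long-read/short-read transcript models with truth
#'
#' Builds multi-exon gene models in fixed genome territories; the base
#' isoform of each gene forms the (reduced) reference annotation. Extra
#' isoforms are constructed by applying a sampled AS edit to the base
#' (recorded as event truth and as the expected structural category
#' relative to the reference). Additional novel-category transcripts
#' (ISM/NIC/NNC/Antisense/Genic/Intergenic/Fusion) and a short-read
#' transcript set with planted reconstruction statuses are emitted. When a
#' genome is supplied it is edited in place: a long ORF is written into
#' every base isoform, canonical GT-AG dinucleotides at every intron of
#' every emitted transcript.
#'
#' @param cfg A [simulationConfig()].
#' @param genome Optional `DNAStringSet` from [simulateGenome()]; `NULL`
#'   skips all sequence editing (structure-only simulation).
#' @return list with `reference`, `isoseq`, `rnaseq` ([TranscriptSet]s),
#'   `juncCov`, `genome` (edited or `NULL`), `orfTruth` and `truth` (lists
#'   of data.frames: `transcripts`, `loci`, `events`, `reconstruction`).
#' @export
simulateAnnotation <- function(cfg, genome = NULL) {
    set.seed(cfg$seed + 23L)
    nG <- cfg$nGenes
    gpc <- cfg$genesPerChrom
    geneRows <- list(); evRows <- list(); reconRows <- list()
    txRows <- list()
    exRows <- list()      # exon table rows for all sets
    addTx <- function(set, id, gene, chrom, strand, starts, ends,
                      category = NA, event = NA, base = NA) {
        exRows[[length(exRows) + 1L]] <<- data.frame(
            set = set, chrom = chrom, start = starts, end = ends,
            strand = strand, transcript_id = id, gene_id = gene)
        txRows[[length(txRows) + 1L]] <<- data.frame(
            transcript_id = id, gene_id = gene, set = set,
            category = category, event_type = event, base_id = base)
    }
    genes <- list()
    for (i in seq_len(nG)) {
        chrom <- paste0("chr", (i - 1L) %/% gpc + 1L)
        slotStart <- ((i - 1L) %% gpc) * .SLOT
        strand <- sample(c("+", "-"), 1L)
        gid <- sprintf("G%04d", i)
        base <- .baseModel(slotStart, strand)
        baseId <- paste0(gid, ".1")
        addTx("reference", baseId, gid, chrom, strand, base$starts, base$ends)
        addTx("isoseq", baseId, gid, chrom, strand, base$starts, base$ends,
              category = "FSM")
        k <- as.integer(sample(names(cfg$isoformsPerGene), 1L,
                               prob = cfg$isoformsPerGene))
        sigs <- paste(c(base$starts, base$ends), collapse = ",")
        variants <- list()
        v <- 1L
        while (length(variants) < k - 1L && v <= 20L) {
            v <- v + 1L
            type <- sample(names(cfg$eventMix), 1L, prob = cfg$eventMix)
            ed <- .applyEdit(base, strand, type)
            if (is.null(ed)) next
            sig <- paste(c(ed$starts, ed$ends), collapse = ",")
            if (sig %in% sigs) next
            sigs <- c(sigs, sig)
            vid <- paste0(gid, ".", length(variants) + 2L)
            variants[[vid]] <- list(model = ed, type = type)
            addTx("isoseq", vid, gid, chrom, strand, ed$starts, ed$ends,
                  category = .expectedCategory[[type]], event = type,
                  base = baseId)
            evRows[[length(evRows) + 1L]] <- data.frame(
                gene_id = gid, isoform_a = baseId, isoform_b = vid,
                event_type = type)
        }
        ## short-read transcript with planted reconstruction status
        status <- sample(names(cfg$reconstructionMix), 1L,
                         prob = cfg$reconstructionMix)
        rid <- paste0("R.", gid)
        rg <- paste0("RG", substring(gid, 2L))
        n <- length(base$starts)
        if (status == "full") {
            addTx("rnaseq", rid, rg, chrom, strand, base$starts, base$ends)
        } else if (status == "partial") {
            drop <- if (strand == "+") 1L else n   # drop the 5' exon
            addTx("rnaseq", rid, rg, chrom, strand,
                  base$starts[-drop], base$ends[-drop])
        } else {
            s2 <- base$starts; s2[2] <- s2[2] + 12L
            addTx("rnaseq", rid, rg, chrom, strand, s2, base$ends)
        }
        reconRows[[length(reconRows) + 1L]] <- data.frame(
            transcript_id = baseId, status = status, rnaseq_id = rid)
        genes[[gid]] <- list(gid = gid, chrom = chrom, strand = strand,
                             slotStart = slotStart, base = base,
                             baseId = baseId,
                             nIso = 1L + length(variants))
        geneRows[[length(geneRows) + 1L]] <- data.frame(
            gene_id = gid, n_isoforms = 1L + length(variants))
    }
    ## constructed novel-category transcripts
    nNovel <- round(cfg$novelPerGene * nG)
    novelCats <- if (nNovel > 0)
        sample(names(cfg$novelMix), nNovel, replace = TRUE,
               prob = cfg$novelMix) else character(0)
    gidAll <- names(genes)
    strandOf <- vapply(genes, `[[`, character(1), "strand")
    chromOf <- vapply(genes, `[[`, character(1), "chrom")
    fusable <- which(gidAll[-length(gidAll)] != "" &
                     chromOf[-length(gidAll)] == chromOf[-1L] &
                     strandOf[-length(gidAll)] == strandOf[-1L])
    geneIsoCount <- setNames(vapply(genes, `[[`, integer(1), "nIso"), gidAll)
    for (q in seq_along(novelCats)) {
        cat <- novelCats[q]
        g <- genes[[sample(gidAll, 1L)]]
        b <- g$base; n <- length(b$starts)
        id <- sprintf("NV%04d", q)
        switch(cat,
            ISM = {
                drop <- 1L   # drop the genomically-first exon
                addTx("isoseq", id, g$gid, g$chrom, g$strand,
                      b$starts[-drop], b$ends[-drop], category = "ISM",
                      base = g$baseId)
                geneIsoCount[g$gid] <- geneIsoCount[g$gid] + 1L
            },
            NIC = {
                j <- sample(2:(n - 1L), 1L)
                addTx("isoseq", id, g$gid, g$chrom, g$strand,
                      b$starts[-j], b$ends[-j], category = "NIC",
                      base = g$baseId)
                geneIsoCount[g$gid] <- geneIsoCount[g$gid] + 1L
            },
            NNC = {
                j <- sample(2:(n - 1L), 1L)
                e2 <- b$ends; s2 <- b$starts
                if (g$strand == "+") e2[j] <- e2[j] + sample(100:150, 1L)
                else s2[j] <- s2[j] - sample(100:150, 1L)
                addTx("isoseq", id, g$gid, g$chrom, g$strand, s2, e2,
                      category = "NNC", base = g$baseId)
                geneIsoCount[g$gid] <- geneIsoCount[g$gid] + 1L
            },
            Antisense = {
                anti <- if (g$strand == "+") "-" else "+"
                addTx("isoseq", id, paste0("NA_", id), g$chrom, anti,
                      b$starts[2], b$ends[2], category = "Antisense")
            },
            Genic = {
                lo <- b$ends[2] + 60L
                addTx("isoseq", id, paste0("NG_", id), g$chrom, g$strand,
                      lo, lo + 120L, category = "Genic")
            },
            Intergenic = {
                lo <- g$slotStart + 22000L + sample(0:1500, 1L)
                addTx("isoseq", id, paste0("NI_", id), g$chrom, g$strand,
                      c(lo, lo + 400L), c(lo + 150L, lo + 550L),
                      category = "Intergenic")
            },
            Fusion = {
                if (!length(fusable)) next
                f <- fusable[sample.int(length(fusable), 1L)]
                g1 <- genes[[gidAll[f]]]; g2 <- genes[[gidAll[f + 1L]]]
                n1 <- length(g1$base$starts)
                addTx("isoseq", id, paste0("NF_", id), g1$chrom, g1$strand,
                      c(g1$base$starts[(n1 - 1L):n1], g2$base$starts[1:2]),
                      c(g1$base$ends[(n1 - 1L):n1], g2$base$ends[1:2]),
                      category = "Fusion")
            })
    }
    ex <- do.call(rbind, exRows)
    mk <- function(setName) {
        sub <- ex[ex$set == setName, , drop = FALSE]
        TranscriptSet(sub[, c("chrom", "start", "end", "strand",
                              "transcript_id", "gene_id")])
    }
    reference <- mk("reference"); isoseq <- mk("isoseq"); rnaseq <- mk("rnaseq")
    ## junction coverage for every isoseq junction
    jc <- junctionChain(isoseq)
    ch <- txChrom(isoseq); sd <- txStrand(isoseq)
    juncCov <- do.call(rbind, lapply(seq_along(jc), function(i) {
        j <- jc[[i]]
        if (!nrow(j)) return(NULL)
        data.frame(chrom = unname(ch[i]), strand = unname(sd[i]),
                   donor = j$donor, acceptor = j$acceptor)
    }))
    if (!is.null(juncCov)) {
        juncCov <- unique(juncCov)
        juncCov$coverage <- sample(cfg$covRange[1]:cfg$covRange[2],
                                   nrow(juncCov), replace = TRUE)
        rownames(juncCov) <- NULL
    } else {
        juncCov <- data.frame(chrom = character(0), strand = character(0),
                              donor = integer(0), acceptor = integer(0),
                              coverage = integer(0))
    }
    orfTruth <- NULL
    if (!is.null(genome)) {
        genome <- .plantSequences(cfg, genome, genes, isoseq, reference,
                                  rnaseq)
        orfTruth <- attr(genome, "orfTruth")
        attr(genome, "orfTruth") <- NULL
    }
    loci <- do.call(rbind, geneRows)
    loci$n_isoforms <- as.integer(geneIsoCount[loci$gene_id])
    list(reference = reference, isoseq = isoseq, rnaseq = rnaseq,
         juncCov = juncCov, genome = genome, orfTruth = orfTruth,
         truth = list(
             transcripts = do.call(rbind, txRows),
             loci = loci,
             events = if (length(evRows)) do.call(rbind, evRows) else
                 data.frame(gene_id = character(0), isoform_a = character(0),
                            isoform_b = character(0),
                            event_type = character(0)),
             reconstruction = do.call(rbind, reconRows)))
}

## write ORFs into base isoforms and GT-AG at every intron of every model
.plantSequences <- function(cfg, genome, genes, isoseq, reference, rnaseq) {
    set.seed(cfg$seed + 37L)
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1L, paste,
                    collapse = "")
    nonStop <- setdiff(codons, c("TAA", "TAG", "TGA"))
    edits <- list()  # per chrom: data.frame(start, value)
    addEdit <- function(chrom, start, value) {
        edits[[chrom]] <<- rbind(edits[[chrom]],
                                 data.frame(start = start, value = value))
    }
    orfRows <- list()
    for (g in genes) {
        b <- g$base
        w <- b$ends - b$starts + 1L
        L <- sum(w)
        utr5 <- 12L; utr3 <- 45L
        ncod <- (L - utr5 - utr3) %/% 3L
        cds <- paste0("ATG",
                      paste(sample(nonStop, ncod - 2L, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
        spliced <- paste0(
            paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                  collapse = ""),
            cds,
            paste(sample(c("A", "C", "G", "T"), L - utr5 - 3L * ncod,
                         replace = TRUE), collapse = ""))
        ## ensure no ATG in the 5' UTR (keeps the planted ORF 5'-most)
        spliced <- paste0(gsub("ATG", "ACG",
                               substr(spliced, 1L, utr5 + 2L), fixed = TRUE),
                          substr(spliced, utr5 + 3L, L))
        ## write spliced segments exon by exon (transcript order)
        ord <- if (g$strand == "+") seq_along(w) else rev(seq_along(w))
        pos <- 0L
        for (j in ord) {
            seg <- substr(spliced, pos + 1L, pos + w[j])
            if (g$strand == "-")
                seg <- as.character(reverseComplement(DNAString(seg)))
            addEdit(g$chrom, b$starts[j], seg)
            pos <- pos + w[j]
        }
        orfRows[[length(orfRows) + 1L]] <- data.frame(
            transcript_id = g$baseId, gene_id = g$gid,
            orf_start = utr5, orf_end = utr5 + 3L * ncod,
            spliced_length = L)
    }
    ## canonical GT-AG at every intron of every emitted model
    for (ts in list(isoseq, reference, rnaseq)) {
        jc <- junctionChain(ts)
        ch <- txChrom(ts); sd <- txStrand(ts)
        for (i in seq_along(jc)) {
            j <- jc[[i]]
            if (!nrow(j)) next
            for (r in seq_len(nrow(j))) {
                if (sd[i] == "+") {
                    addEdit(ch[i], j$donor[r] + 1L, "GT")
                    addEdit(ch[i], j$acceptor[r] - 2L, "AG")
                } else {
                    addEdit(ch[i], j$donor[r] - 2L, "AC")  # revcomp GT
                    addEdit(ch[i], j$acceptor[r] + 1L, "CT")  # revcomp AG
                }
            }
        }
    }
    for (chrom in names(edits)) {
        ed <- edits[[chrom]]
        ed$end <- ed$start + nchar(ed$value) - 1L
        ed <- ed[!duplicated(paste(ed$start, ed$value)), , drop = FALSE]
        ## drop any edit fully covered by an identical earlier one; then
        ## resolve residual overlaps by keeping the first (exon writes come
        ## first, so junction dinucleotides never clobber coding sequence)
        ed <- ed[order(ed$start, -nchar(ed$value)), , drop = FALSE]
        keep <- rep(TRUE, nrow(ed))
        lastEnd <- -1L
        for (i in seq_len(nrow(ed))) {
            if (ed$start[i] <= lastEnd) keep[i] <- FALSE
            else lastEnd <- ed$end[i]
        }
        ed <- ed[keep, , drop = FALSE]
        genome[[chrom]] <- replaceAt(
            genome[[chrom]],
            at = IRanges(ed$start, ed$end),
            value = DNAStringSet(ed$value))
    }
    attr(genome, "orfTruth") <- do.call(rbind, orfRows)
    genome
}

#' Simulate isoform counts with planted sex-biased usage shifts
#'
#' Negative-binomial counts (Var = mu + phi mu^2) per isoform and sample.
#' Switch genes receive sex-specific usage on the (base, first variant)
#' pair: the female-preferred isoform gets molar fraction `0.5 + dIF/2`
#' in females and `0.5 - dIF/2` in males (other isoforms share the rest
#' equally, identical across sexes), so the expected TPM-scale dIF of the
#' pair is exactly +/- `plantedDIF`. Expected counts are proportional to
#' molar usage times effective length; effective length equals spliced
#' length.
#'
#' @param cfg A [simulationConfig()].
#' @param ann Output of [simulateAnnotation()].
#' @return list with `ie` (an [IsoformExperiment] over the base+variant
#'   isoforms), `design` data.frame, and truth data.frames `switches`
#'   (per gene) and `usage` (per isoform expected molar fractions).
#' @export
simulateCounts <- function(cfg, ann) {
    set.seed(cfg$seed + 31L)
    tx <- ann$truth$transcripts
    quant <- tx[tx$set == "isoseq" & grepl("^G", tx$gene_id), , drop = FALSE]
    quant <- quant[grepl("\\.\\d+$", quant$transcript_id), , drop = FALSE]
    lens <- splicedLength(ann$isoseq)[quant$transcript_id]
    genes <- unique(quant$gene_id)
    multi <- genes[vapply(genes, function(g)
        sum(quant$gene_id == g) >= 2L, logical(1))]
    nSwitch <- round(cfg$switchFraction * length(multi))
    switchGenes <- if (nSwitch > 0)
        sort(multi[sample.int(length(multi), nSwitch)]) else character(0)
    theta <- matrix(0, nrow(quant), 2L,
                    dimnames = list(quant$transcript_id, c("F", "M")))
    swRows <- list()
    for (g in genes) {
        ids <- quant$transcript_id[quant$gene_id == g]
        k <- length(ids)
        if (g %in% switchGenes) {
            d <- cfg$plantedDIF
            restMass <- if (k > 2L) 0.1 * (k - 2L) else 0
            hi <- (1 - restMass) / 2 + d / 2
            lo <- (1 - restMass) / 2 - d / 2
            femPref <- sample(ids[1:2], 1L)
            malPref <- setdiff(ids[1:2], femPref)
            theta[femPref, "F"] <- hi; theta[femPref, "M"] <- lo
            theta[malPref, "F"] <- lo; theta[malPref, "M"] <- hi
            if (k > 2L) theta[ids[3:k], ] <- 0.1
            swRows[[length(swRows) + 1L]] <- data.frame(
                gene_id = g, is_switch = TRUE, planted_dIF = d,
                female_isoform = femPref, male_isoform = malPref)
        } else {
            u <- runif(k, 0.2, 1)
            u <- u / sum(u)
            theta[ids, "F"] <- u; theta[ids, "M"] <- u
            swRows[[length(swRows) + 1L]] <- data.frame(
                gene_id = g, is_switch = FALSE, planted_dIF = 0,
                female_isoform = NA_character_, male_isoform = NA_character_)
        }
    }
    wGene <- setNames(rlnorm(length(genes), meanlog = 0, sdlog = 1), genes)
    w <- wGene[quant$gene_id]
    nRep <- cfg$nReplicates
    samples <- c(paste0("F", seq_len(nRep)), paste0("M", seq_len(nRep)))
    sex <- rep(c("Female", "Male"), each = nRep)
    muF <- w * theta[, "F"] * lens
    muM <- w * theta[, "M"] * lens
    muF <- cfg$librarySize * muF / sum(muF)
    muM <- cfg$librarySize * muM / sum(muM)
    counts <- matrix(0, nrow(quant), length(samples),
                     dimnames = list(quant$transcript_id, samples))
    for (s in seq_along(samples)) {
        mu <- if (sex[s] == "Female") muF else muM
        counts[, s] <- if (cfg$dispersion > 0)
            rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
        else rpois(length(mu), mu)
    }
    ie <- IsoformExperiment(counts, geneId = quant$gene_id,
                            effectiveLength = lens, sex = sex)
    list(ie = ie,
         design = data.frame(sample_id = samples, sex = sex),
         truth = list(
             switches = do.call(rbind, swRows),
             usage = data.frame(isoform_id = quant$transcript_id,
                                gene_id = quant$gene_id,
                                theta_female = theta[, "F"],
                                theta_male = theta[, "M"],
                                expected_dIF = theta[, "F"] - theta[, "M"],
                                row.names = NULL)))
}

#' Simulate a motif and implant its consensus upstream of gene TSSs
#'
#' Writes a near-one-hot PFM (97/1/1/1 counts per column) and implants its
#' consensus, strand-aware, at a recorded offset 200-2000 bp upstream of
#' the base-isoform TSS in a `motifPlantRate` fraction of genes.
#'
#' @param cfg A [simulationConfig()].
#' @param genome `DNAStringSet` (typically the edited genome from
#'   [simulateAnnotation()]).
#' @param ann Output of [simulateAnnotation()].
#' @return list: `genome` (edited), `pfm` ([PositionFrequencyMatrix]) and
#'   `truth` data.frame (`gene_id`, `chrom`, `strand`, `genomic_start`,
#'   `tss_offset`).
#' @export
simulatePromoters <- function(cfg, genome, ann) {
    set.seed(cfg$seed + 47L)
    w <- cfg$motifWidth
    consensus <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                       collapse = "")
    counts <- matrix(1, 4L, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    cvec <- strsplit(consensus, "")[[1]]
    for (j in seq_len(w)) counts[cvec[j], j] <- 97
    pfm <- PositionFrequencyMatrix("SIMTF1", counts)
    ref <- .plainTx(ann$reference)
    rows <- list()
    edits <- list()
    for (t in ref) {
        if (runif(1) > cfg$motifPlantRate) next
        off <- sample(200:2000, 1L)
        if (t$strand == "+") {
            tss <- min(t$starts)
            gs <- tss - off
            val <- consensus
        } else {
            tss <- max(t$ends)
            gs <- tss + off - w + 1L
            val <- as.character(reverseComplement(DNAString(consensus)))
        }
        edits[[length(edits) + 1L]] <- data.frame(
            chrom = t$chrom, start = gs, value = val)
        rows[[length(rows) + 1L]] <- data.frame(
            gene_id = t$gene, chrom = t$chrom, strand = t$strand,
            genomic_start = gs, tss_offset = off)
    }
    if (length(edits)) {
        ed <- do.call(rbind, edits)
        for (chrom in unique(ed$chrom)) {
            e <- ed[ed$chrom == chrom, , drop = FALSE]
            genome[[chrom]] <- replaceAt(
                genome[[chrom]],
                at = IRanges(e$start, e$start + nchar(e$value) - 1L),
                value = DNAStringSet(e$value))
        }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_id = character(0), chrom = character(0),
                   strand = character(0), genomic_start = integer(0),
                   tss_offset = integer(0))
    rownames(truth) <- NULL
    list(genome = genome, pfm = pfm, truth = truth)
}

#' Simulate a complete dataset with ground truth
#'
#' Composes [simulateGenome()], [simulateAnnotation()],
#' [simulatePromoters()] and [simulateCounts()].
#'
#' @param cfg A [simulationConfig()].
#' @param sequences Generate and edit genome sequence (default TRUE; FALSE
#'   gives a fast structure+counts-only dataset).
#' @return list: `genome`, `reference`, `isoseq`, `rnaseq`, `juncCov`,
#'   `ie`, `design`, `pfm`, `truth` (all truth tables), `config`.
#' @export
simulateDataset <- function(cfg, sequences = TRUE) {
    genome <- if (sequences) simulateGenome(cfg) else NULL
    ann <- simulateAnnotation(cfg, genome)
    pr <- if (sequences) simulatePromoters(cfg, ann$genome, ann) else NULL
    cnt <- simulateCounts(cfg, ann)
    list(genome = if (sequences) pr$genome else NULL,
         reference = ann$reference, isoseq = ann$isoseq,
         rnaseq = ann$rnaseq, juncCov = ann$juncCov,
         ie = cnt$ie, design = cnt$design,
         pfm = if (sequences) pr$pfm else NULL,
         truth = c(ann$truth, cnt$truth,
                   list(orfs = ann$orfTruth,
                        motifs = if (sequences) pr$truth else NULL)),
         config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `reference.gtf`, `isoseq.gtf`, `rnaseq.gtf`,
#' `junc_cov.tsv`, `counts.tsv`, `design.tsv`, `motifs.jaspar` and
#' `truth/*.tsv`.
#'
#' @param sim Output of [simulateDataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(file.path(dir, "truth"), showWarnings = FALSE,
               recursive = TRUE)
    if (!is.null(sim$genome))
        writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    writeGTF(sim$reference, file.path(dir, "reference.gtf"))
    writeGTF(sim$isoseq, file.path(dir, "isoseq.gtf"))
    writeGTF(sim$rnaseq, file.path(dir, "rnaseq.gtf"))
    wt <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                         row.names = FALSE)
    wt(sim$juncCov, file.path(dir, "junc_cov.tsv"))
    cnt <- data.frame(isoform_id = rownames(sim$ie),
                      gene_id = unname(geneIds(sim$ie)),
                      effective_length = unname(effectiveLength(sim$ie)),
                      assay(sim$ie, "counts"), check.names = FALSE)
    wt(cnt, file.path(dir, "counts.tsv"))
    wt(sim$design, file.path(dir, "design.tsv"))
    if (!is.null(sim$pfm)) writeJaspar(sim$pfm, file.path(dir, "motifs.jaspar"))
    for (nm in names(sim$truth)) {
        if (!is.null(sim$truth[[nm]]))
            wt(sim$truth[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")))
    }
    invisible(dir)
}

#' Random classification cases for oracle validation
#'
#' Generates small independent loci (each pair of loci on its own
#' chromosome so that fusion cases exist) with 1-4 reference transcripts
#' and a panel of query transcripts per locus: copies, truncations,
#' exon-skips, boundary perturbations, antisense/intronic/intergenic
#' placements, bridging (fusion) queries and randomly perturbed models
#' (<= 5 junctions each). No labels are recorded: the point is agreement
#' between [classifyTranscripts()] and [bruteForceClassify()].
#'
#' @param nLoci Number of reference loci.
#' @param seed Integer seed.
#' @return list with `reference` and `query` [TranscriptSet]s.
#' @export
simulateClassificationCases <- function(nLoci, seed) {
    set.seed(seed)
    refRows <- list(); qRows <- list()
    addRow <- function(store, id, gene, chrom, strand, starts, ends) {
        df <- data.frame(chrom = chrom, start = starts, end = ends,
                         strand = strand, transcript_id = id, gene_id = gene)
        if (store == "ref") refRows[[length(refRows) + 1L]] <<- df
        else qRows[[length(qRows) + 1L]] <<- df
    }
    mkBase <- function(offset) {
        nEx <- sample(3:6, 1L)
        exL <- sample(80:200, nEx, replace = TRUE)
        inL <- sample(200:600, nEx - 1L, replace = TRUE)
        starts <- integer(nEx); ends <- integer(nEx)
        pos <- offset + 1L
        for (j in seq_len(nEx)) {
            starts[j] <- pos; ends[j] <- pos + exL[j] - 1L
            pos <- ends[j] + if (j < nEx) inL[j] + 1L else 0L
        }
        list(starts = starts, ends = ends)
    }
    lastModels <- list()
    for (i in seq_len(nLoci)) {
        chrom <- paste0("L", (i - 1L) %/% 2L + 1L)
        offset <- ((i - 1L) %% 2L) * 50000L + 2000L
        strand <- sample(c("+", "-"), 1L)
        gid <- sprintf("RG%04d", i)
        base <- mkBase(offset)
        n <- length(base$starts)
        models <- list(base)
        addRow("ref", paste0(gid, ".1"), gid, chrom, strand,
               base$starts, base$ends)
        nRef <- sample(1:4, 1L)
        for (v in seq_len(nRef - 1L)) {
            op <- sample(c("skip", "alt", "trunc"), 1L)
            m <- base
            if (op == "skip" && n >= 3L) {
                j <- sample(2:(n - 1L), 1L)
                m <- list(starts = base$starts[-j], ends = base$ends[-j])
            } else if (op == "alt") {
                j <- sample(seq_len(n - 1L), 1L)
                m$ends[j] <- m$ends[j] + sample(20:60, 1L)
            } else {
                keep <- sort(sample(seq_len(n), max(2L, n - 1L)))
                keep <- min(keep):max(keep)
                m <- list(starts = base$starts[keep], ends = base$ends[keep])
            }
            addRow("ref", paste0(gid, ".", v + 1L), gid, chrom, strand,
                   m$starts, m$ends)
            models[[length(models) + 1L]] <- m
        }
        ## query panel
        qid <- function(tag) paste0("Q.", gid, ".", tag)
        addRow("q", qid("copy"), "q", chrom, strand, base$starts, base$ends)
        if (n >= 3L) {
            keep <- 2:n
            addRow("q", qid("trunc"), "q", chrom, strand,
                   base$starts[keep], base$ends[keep])
            j <- sample(2:(n - 1L), 1L)
            addRow("q", qid("skip"), "q", chrom, strand,
                   base$starts[-j], base$ends[-j])
        }
        m <- base
        j <- sample(seq_len(n - 1L), 1L)
        m$ends[j] <- m$ends[j] + sample(5:15, 1L)
        addRow("q", qid("pert"), "q", chrom, strand, m$starts, m$ends)
        anti <- if (strand == "+") "-" else "+"
        addRow("q", qid("anti"), "q", chrom, anti,
               base$starts[1], base$ends[1])
        addRow("q", qid("intr"), "q", chrom, strand,
               base$ends[1] + 30L, base$ends[1] + 90L)
        addRow("q", qid("inter"), "q", chrom, strand,
               offset + 30000L, offset + 30200L)
        mono <- sample(seq_len(n), 1L)
        addRow("q", qid("mono"), "q", chrom, strand,
               base$starts[mono] + 5L,
               max(base$starts[mono] + 10L, base$ends[mono] - 5L))
        ## random 1-3 fold perturbation of a reference model
        m <- models[[sample(length(models), 1L)]]
        for (r in seq_len(sample(1:3, 1L))) {
            nn <- length(m$starts)
            what <- sample(c("shift", "drop"), 1L)
            if (what == "shift") {
                j <- sample(nn, 1L)
                m$starts[j] <- m$starts[j] + sample(-10:10, 1L)
                if (m$starts[j] > m$ends[j] - 5L) m$starts[j] <- m$ends[j] - 5L
                if (j > 1L && m$starts[j] <= m$ends[j - 1L] + 1L)
                    m$starts[j] <- m$ends[j - 1L] + 2L
            } else if (nn >= 2L) {
                j <- sample(nn, 1L)
                m <- list(starts = m$starts[-j], ends = m$ends[-j])
            }
        }
        addRow("q", qid("rand"), "q", chrom, strand, m$starts, m$ends)
        ## fusion bridging the two loci on this chromosome
        if (i %% 2L == 0L && length(lastModels) &&
            lastModels$chrom == chrom && lastModels$strand == strand) {
            b1 <- lastModels$base; n1 <- length(b1$starts)
            addRow("q", qid("fus"), "q", chrom, strand,
                   c(b1$starts[n1], base$starts[1]),
                   c(b1$ends[n1], base$ends[1]))
        }
        lastModels <- list(chrom = chrom, strand = strand, base = base)
    }
    list(reference = TranscriptSet(do.call(rbind, refRows)),
         query = TranscriptSet(do.call(rbind, qRows)))
}

#' Exhaustive two-isoform configurations from a coordinate grid
#'
#' Builds every transcript whose exon boundaries are an even-sized
#' ascending subset of `positions` (up to `maxExons` exons): subset
#' `p1 < p2 < ...` maps to exons `[p1, p2-1], [p3, p4-1], ...`. All
#' unordered pairs of distinct transcripts are valid two-isoform loci.
#'
#' @param positions Increasing integer coordinate grid (>= 4 values).
#' @param maxExons Maximum exons per transcript (default 4).
#' @param strand Strand for the constructed transcripts.
#' @return A [TranscriptSet] on chromosome `"grid"`, gene `"gridgene"`.
#' @export
enumeratePairGrid <- function(positions, maxExons = 4L, strand = "+") {
    positions <- sort(unique(as.integer(positions)))
    rows <- list(); k <- 0L
    for (ne in seq_len(maxExons)) {
        if (2L * ne > length(positions)) break
        sel <- combn(positions, 2L * ne)
        for (c1 in seq_len(ncol(sel))) {
            p <- sel[, c1]
            starts <- p[seq(1L, 2L * ne, by = 2L)]
            ends <- p[seq(2L, 2L * ne, by = 2L)] - 1L
            k <- k + 1L
            rows[[k]] <- data.frame(
                chrom = "grid", start = starts, end = ends, strand = strand,
                transcript_id = sprintf("cfg%05d", k), gene_id = "gridgene")
        }
    }
    TranscriptSet(do.call(rbind, rows))
}
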