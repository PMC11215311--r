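## TPM and isoform-fraction computation, differential isoform usage between
## sexes (Welch or exact/sampled permutation test on per-replicate IF),
## sex-biased isoform and isoform-switch calling, key-gene filtering and
## the four-way length categorisation with dIF ranking.

#' Transcripts-per-million matrix
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j(c_j / l_j)` per sample. Column sums
#' equal 1e6 whenever the sample has any count; an all-zero sample yields
#' an all-zero column with a warning.
#'
#' @param ie An [IsoformExperiment] (or a counts matrix, with
#'   `effectiveLength` supplied).
#' @param effectiveLength Required when `ie` is a plain matrix.
#' @return Numeric matrix, same shape as the counts.
#' @export
computeTPM <- function(ie, effectiveLength = NULL) {
    if (is(ie, "IsoformExperiment")) {
        cnt <- assay(ie, "counts")
        len <- rowData(ie)$effective_length
    } else {
        cnt <- as.matrix(ie)
        len <- effectiveLength
        if (is.null(len)) stop("effectiveLength required")
    }
    if (any(len <= 0)) stop("effective lengths must be positive")
    rate <- cnt / len
    tot <- colSums(rate)
    if (any(tot == 0)) {
        warning("all-zero sample(s): ",
                paste(colnames(cnt)[tot == 0], collapse = ", "))
        tot[tot == 0] <- 1
    }
    sweep(rate, 2L, tot, "/") * 1e6
}

#' Isoform fraction matrix
#'
#' IF = isoform TPM / parent-gene TPM (gene TPM = sum over its isoforms).
#' Undefined (NA) when the gene TPM is zero in that sample; defined IFs of
#' a gene sum to 1 per sample.
#'
#' @param tpm TPM matrix (isoforms x samples).
#' @param geneId Character vector of parent genes, one per row.
#' @return Numeric matrix of isoform fractions.
#' @export
isoformFraction <- function(tpm, geneId) {
    geneTPM <- rowsum(tpm, geneId)
    denom <- geneTPM[as.character(geneId), , drop = FALSE]
    ifm <- tpm / denom
    ifm[denom == 0] <- NA_real_
    dimnames(ifm) <- dimnames(tpm)
    ifm
}

## exact/sampled permutation machinery: weight matrix whose columns encode
## mean(F-assigned) - mean(M-assigned) for each label assignment
.permWeights <- function(n, nF, maxExact = 20000L, nPerm = 1000L,
                         seed = NULL) {
    if (choose(n, nF) <= maxExact) {
        sel <- combn(n, nF)
        exact <- TRUE
    } else {
        if (is.null(seed)) stop("seed required for sampled permutations")
        rs <- .Random.seed_save()
        on.exit(.Random.seed_restore(rs), add = TRUE)
        set.seed(seed)
        sel <- replicate(nPerm, sample.int(n, nF))
        exact <- FALSE
    }
    W <- matrix(-1 / (n - nF), nrow = n, ncol = ncol(sel))
    for (k in seq_len(ncol(sel))) W[sel[, k], k] <- 1 / nF
    list(W = W, exact = exact)
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
    invisible(NULL)
}

#' Differential isoform usage between sexes
#'
#' Computes per-isoform condition-mean isoform fractions, the effect size
#' `dIF = mean IF(Female) - mean IF(Male)`, a two-sided p-value, and
#' Benjamini-Hochberg q-values across all tested isoforms. Two test modes:
#' `"welch"` (unequal-variance t-test on per-replicate IF) and
#' `"permutation"` (condition-label permutation of the mean difference;
#' all `choose(n, nF)` assignments are enumerated exactly when feasible,
#' otherwise `nPerm` random assignments are drawn under `seed` with the
#' add-one estimator). Isoforms with fewer than two defined IF replicates
#' on either side are left untested (`p = NA`), as are isoforms of
#' single-isoform genes (their IF is identically 1, so usage carries no
#' information; only multi-isoform loci enter the screen). Genes whose TPM
#' is zero in
#' every sample are dropped before testing.
#'
#' @param ie An [IsoformExperiment].
#' @param method `"welch"` or `"permutation"`.
#' @param nPerm Random permutations when exact enumeration is infeasible.
#' @param seed Seed for sampled permutations (exact mode needs none).
#' @param maxExact Enumeration cap on `choose(n, nF)`.
#' @return data.frame: `isoform_id`, `gene_id`, `IF_female`, `IF_male`,
#'   `dIF`, `p_value`, `q_value`, `mean_TPM_female`, `mean_TPM_male`.
#' @export
testIsoformUsage <- function(ie, method = c("welch", "permutation"),
                             nPerm = 1000L, seed = NULL,
                             maxExact = 20000L) {
    method <- match.arg(method)
    tpm <- computeTPM(ie)
    gid <- geneIds(ie)
    ## gene-level TPM > 0 retention filter
    gTPM <- rowsum(tpm, gid)
    keepGene <- rownames(gTPM)[rowSums(gTPM) > 0]
    keep <- as.character(gid) %in% keepGene
    tpm <- tpm[keep, , drop = FALSE]
    gid <- gid[keep]
    ifm <- isoformFraction(tpm, gid)
    sex <- sampleSex(ie)
    isF <- sex == "Female"; isM <- sex == "Male"
    mF <- rowMeans(ifm[, isF, drop = FALSE], na.rm = TRUE)
    mM <- rowMeans(ifm[, isM, drop = FALSE], na.rm = TRUE)
    mF[is.nan(mF)] <- NA; mM[is.nan(mM)] <- NA
    dIF <- mF - mM
    tpmF <- rowMeans(tpm[, isF, drop = FALSE])
    tpmM <- rowMeans(tpm[, isM, drop = FALSE])
    nDefF <- rowSums(!is.na(ifm[, isF, drop = FALSE]))
    nDefM <- rowSums(!is.na(ifm[, isM, drop = FALSE]))
    ## only isoforms of multi-isoform genes carry usage information
    multiIso <- as.character(gid) %in%
        names(which(table(as.character(gid)) >= 2L))
    testable <- nDefF >= 2L & nDefM >= 2L & multiIso
    p <- rep(NA_real_, nrow(ifm))
    if (method == "welch") {
        vF <- apply(ifm[, isF, drop = FALSE], 1L, stats::var, na.rm = TRUE)
        vM <- apply(ifm[, isM, drop = FALSE], 1L, stats::var, na.rm = TRUE)
        se2 <- vF / nDefF + vM / nDefM
        tt <- dIF / sqrt(se2)
        df <- se2^2 / ((vF / nDefF)^2 / (nDefF - 1L) +
                       (vM / nDefM)^2 / (nDefM - 1L))
        pw <- 2 * pt(-abs(tt), df)
        degenerate <- testable & (is.na(se2) | se2 == 0)
        pw[degenerate] <- ifelse(abs(dIF[degenerate]) < 1e-12, 1, 0)
        p[testable] <- pw[testable]
    } else {
        ## group isoforms by their defined-replicate pattern so one weight
        ## matrix serves each pattern
        pat <- apply(!is.na(ifm), 1L, paste, collapse = "")
        for (pp in unique(pat[testable])) {
            rows <- which(pat == pp & testable)
            def <- !is.na(ifm[rows[1L], ])
            nF <- sum(def & isF); nM <- sum(def & isM)
            idx <- which(def)
            ## order so the weight construction sees F/M positions
            pw <- .permWeights(length(idx), nF, maxExact = maxExact,
                               nPerm = nPerm, seed = seed)
            ## arrange columns: first nF weights belong to "assigned F"
            X <- ifm[rows, idx, drop = FALSE]
            ## put true F columns first so the identity assignment is col 1
            ordx <- c(which(isF[idx]), which(isM[idx]))
            X <- X[, ordx, drop = FALSE]
            D <- X %*% pw$W
            obs <- X %*% c(rep(1 / nF, nF), rep(-1 / nM, nM))
            tol <- 1e-12
            extreme <- abs(D) >= (abs(as.numeric(obs)) - tol)
            if (pw$exact) {
                p[rows] <- rowMeans(extreme)
            } else {
                p[rows] <- (1 + rowSums(extreme)) / (ncol(D) + 1)
            }
        }
    }
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
    data.frame(isoform_id = rownames(ifm), gene_id = as.character(gid),
               IF_female = unname(mF), IF_male = unname(mM),
               dIF = unname(dIF), p_value = unname(p), q_value = unname(q),
               mean_TPM_female = unname(tpmF), mean_TPM_male = unname(tpmM),
               row.names = NULL)
}

#' Call significantly sex-biased isoforms
#'
#' female-biased iff `dIF > minDif`, `q < fdr` and mean TPM exceeds
#' `minTPM` in both sexes; male-biased symmetrically with `dIF < -minDif`;
#' otherwise none.
#'
#' @param usage Output of [testIsoformUsage()].
#' @param minDif dIF magnitude threshold (default 0.1).
#' @param fdr FDR threshold on q-values (default 0.05).
#' @param minTPM Mean-TPM floor required in both sexes (default 1).
#' @return `usage` with an added `bias` column
#'   (`"female"`/`"male"`/`"none"`).
#' @export
callSexBiased <- function(usage, minDif = 0.1, fdr = 0.05, minTPM = 1) {
    expr <- !is.na(usage$q_value) &
        usage$mean_TPM_female > minTPM & usage$mean_TPM_male > minTPM
    bias <- rep("none", nrow(usage))
    bias[expr & usage$dIF > minDif & usage$q_value < fdr] <- "female"
    bias[expr & usage$dIF < -minDif & usage$q_value < fdr] <- "male"
    usage$bias <- bias
    usage
}

#' Call isoform-switching genes
#'
#' A gene switches when it has at least one significantly female-biased and
#' one male-biased isoform (opposite dIF signs). The top female-biased
#' isoform is the one with the largest dIF, the top male-biased the one
#' with the smallest.
#'
#' @param usage Output of [callSexBiased()].
#' @return data.frame per gene: `gene_id`, `n_female_biased`,
#'   `n_male_biased`, `is_switch`, `female_isoform`, `male_isoform`,
#'   `female_dIF`, `male_dIF`.
#' @export
callSwitchGenes <- function(usage) {
    genes <- sort(unique(usage$gene_id))
    rows <- lapply(genes, function(g) {
        u <- usage[usage$gene_id == g, , drop = FALSE]
        f <- u[u$bias == "female", , drop = FALSE]
        m <- u[u$bias == "male", , drop = FALSE]
        fi <- if (nrow(f)) f$isoform_id[which.max(f$dIF)] else NA_character_
        mi <- if (nrow(m)) m$isoform_id[which.min(m$dIF)] else NA_character_
        data.frame(gene_id = g, n_female_biased = nrow(f),
                   n_male_biased = nrow(m),
                   is_switch = nrow(f) >= 1L && nrow(m) >= 1L,
                   female_isoform = fi, male_isoform = mi,
                   female_dIF = if (nrow(f)) max(f$dIF) else NA_real_,
                   male_dIF = if (nrow(m)) min(m$dIF) else NA_real_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Key-gene filter on switching genes
#'
#' A switching gene is key when (a) every sex-biased isoform of the gene
#' has mean TPM above `keyTPM` in at least one sex, (b) the protein-coding
#' regions of the top female- and male-biased isoforms differ, and (c) the
#' pair's events include an ATSS or ATTS inside a coding region.
#'
#' @param switches Output of [callSwitchGenes()].
#' @param usage Output of [callSexBiased()].
#' @param orfs Output of [predictOrfs()] (named by isoform).
#' @param events Event rows for the switch pairs with `in_coding_region`
#'   filled (from [annotateLocus()] with `cds`).
#' @param keyTPM TPM threshold (default 20).
#' @return `switches` with added logical `is_key` (NA rows are skipped with
#'   a warning when ORF/event information is missing).
#' @export
keyGeneFilter <- function(switches, usage, orfs, events, keyTPM = 20) {
    isKey <- rep(FALSE, nrow(switches))
    for (i in seq_len(nrow(switches))) {
        if (!switches$is_switch[i]) next
        g <- switches$gene_id[i]
        u <- usage[usage$gene_id == g & usage$bias != "none", , drop = FALSE]
        if (!all(pmax(u$mean_TPM_female, u$mean_TPM_male) > keyTPM)) next
        fi <- switches$female_isoform[i]; mi <- switches$male_isoform[i]
        if (!(fi %in% names(orfs)) || !(mi %in% names(orfs))) {
            warning("missing ORF prediction for gene ", g, "; skipped")
            isKey[i] <- NA
            next
        }
        if (!codingRegionsDiffer(orfs[[fi]], orfs[[mi]])) next
        ev <- events[(events$isoform_a == fi & events$isoform_b == mi) |
                     (events$isoform_a == mi & events$isoform_b == fi), ,
                     drop = FALSE]
        if (!nrow(ev)) {
            warning("no event annotation for switch pair of gene ", g,
                    "; skipped")
            isKey[i] <- NA
            next
        }
        if (anyNA(ev$in_coding_region)) {
            warning("in_coding_region not filled for gene ", g, "; skipped")
            isKey[i] <- NA
            next
        }
        isKey[i] <- any(ev$event_type %in% c("ATSS", "ATTS") &
                        ev$in_coding_region)
    }
    switches$is_key <- isKey
    switches
}

#' Four-way length categorisation and dIF ranking of key genes
#'
#' The top male-biased isoform is `shorter`/`longer` than the top
#' female-biased isoform by spliced length (and vice versa); within each of
#' the four classes genes are ranked by descending |dIF| of the
#' class-defining isoform. Equal lengths give class `n/a` with a warning.
#'
#' @param switches Output of [keyGeneFilter()] (uses rows with
#'   `is_key == TRUE`; pass `onlyKey = FALSE` to rank all switches).
#' @param lengths Named numeric vector of spliced lengths per isoform
#'   (e.g. `splicedLength(ts)`).
#' @param onlyKey Restrict to key genes (default TRUE).
#' @return data.frame per gene: length classes, class-defining dIFs and
#'   within-class ranks (`male_rank`, `female_rank`).
#' @export
categorizeAndRank <- function(switches, lengths, onlyKey = TRUE) {
    rows <- switches[switches$is_switch &
                     (!onlyKey | (!is.na(switches$is_key) & switches$is_key)), ,
                     drop = FALSE]
    if (!nrow(rows))
        return(data.frame(gene_id = character(0),
                          male_length_class = character(0),
                          female_length_class = character(0),
                          male_dIF = numeric(0), female_dIF = numeric(0),
                          male_rank = integer(0), female_rank = integer(0)))
    lm <- lengths[rows$male_isoform]; lf <- lengths[rows$female_isoform]
    mClass <- ifelse(lm < lf, "shorter", ifelse(lm > lf, "longer", "n/a"))
    fClass <- ifelse(lf < lm, "shorter", ifelse(lf > lm, "longer", "n/a"))
    if (any(mClass == "n/a"))
        warning("equal isoform lengths for gene(s): ",
                paste(rows$gene_id[mClass == "n/a"], collapse = ", "))
    out <- data.frame(gene_id = rows$gene_id,
                      male_length_class = mClass,
                      female_length_class = fClass,
                      male_dIF = rows$male_dIF,
                      female_dIF = rows$female_dIF,
                      male_rank = NA_integer_, female_rank = NA_integer_)
    for (cl in c("shorter", "longer")) {
        i <- which(out$male_length_class == cl)
        out$male_rank[i] <- rank(-abs(out$male_dIF[i]), ties.method = "first")
        j <- which(out$female_length_class == cl)
        out$female_rank[j] <- rank(-abs(out$female_dIF[j]),
                                   ties.method = "first")
    }
    rownames(out) <- NULL
    out
}

#' End-to-end sex-biased isoform-switch analysis
#'
#' Runs usage testing, bias and switch calling, ORF prediction, event
#' annotation of switch pairs, key-gene filtering and the length
#' categorisation in one deterministic pass.
#'
#' @param ts [TranscriptSet] of the isoform models being quantified.
#' @param genome `DNAStringSet` (needed for ORFs; pass `NULL` to skip the
#'   ORF/event/key stages).
#' @param ie [IsoformExperiment] of counts for the same isoforms.
#' @param method,nPerm,seed Passed to [testIsoformUsage()].
#' @param minDif,fdr,minTPM Passed to [callSexBiased()].
#' @param keyTPM Passed to [keyGeneFilter()].
#' @param orfMinLen Passed to [predictOrfs()].
#' @return list with `usage`, `switches`, `events`, `orfs`, `classes` and
#'   a `params` record.
#' @export
runSwitchAnalysis <- function(ts, genome, ie,
                              method = "permutation", nPerm = 1000L,
                              seed = 1L, minDif = 0.1, fdr = 0.05,
                              minTPM = 1, keyTPM = 20, orfMinLen = 100L) {
    usage <- testIsoformUsage(ie, method = method, nPerm = nPerm, seed = seed)
    usage <- callSexBiased(usage, minDif = minDif, fdr = fdr, minTPM = minTPM)
    switches <- callSwitchGenes(usage)
    events <- NULL; orfs <- NULL; classes <- NULL
    if (!is.null(genome)) {
        sw <- switches[switches$is_switch, , drop = FALSE]
        pairIso <- unique(c(sw$female_isoform, sw$male_isoform))
        pairIso <- pairIso[pairIso %in% transcriptIds(ts)]
        orfs <- predictOrfs(ts[pairIso], genome, minLen = orfMinLen)
        cds <- lapply(orfs, function(o) if (is.null(o)) NULL else o$cds)
        evRows <- list()
        for (i in seq_len(nrow(sw))) {
            fi <- sw$female_isoform[i]; mi <- sw$male_isoform[i]
            if (!(fi %in% transcriptIds(ts)) || !(mi %in% transcriptIds(ts)))
                next
            ev <- annotatePair(ts[fi], ts[mi], cdsA = cds[[fi]],
                               cdsB = cds[[mi]])
            if (nrow(ev)) evRows[[length(evRows) + 1L]] <- ev
        }
        events <- if (length(evRows)) do.call(rbind, evRows) else
            data.frame(gene_id = character(0), isoform_a = character(0),
                       isoform_b = character(0), event_type = character(0),
                       region_start = integer(0), region_end = integer(0),
                       regions = character(0), owner = character(0),
                       in_coding_region = logical(0))
        switches <- keyGeneFilter(switches, usage, orfs, events,
                                  keyTPM = keyTPM)
        classes <- categorizeAndRank(switches, splicedLength(ts))
    }
    list(usage = usage, switches = switches, events = events, orfs = orfs,
         classes = classes,
         params = list(method = method, nPerm = nPerm, seed = seed,
                       minDif = minDif, fdr = fdr, minTPM = minTPM,
                       keyTPM = keyTPM, orfMinLen = orfMinLen))
}

#' Write the analysis tables with a reproducibility header
#'
#' @param res Output of [runSwitchAnalysis()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
writeSwitchTables <- function(res, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("# isoswitch: seed=", res$params$seed,
                  " method=", res$params$method,
                  " minDif=", res$params$minDif, " fdr=", res$params$fdr,
                  " minTPM=", res$params$minTPM, " keyTPM=", res$params$keyTPM)
    wr <- function(df, name) {
        path <- file.path(dir, name)
        con <- file(path, "w")
        writeLines(hdr, con)
        write.table(format(df, digits = 12), con, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        close(con)
        path
    }
    paths <- c(wr(res$usage, "usage.tsv"), wr(res$switches, "switches.tsv"))
    if (!is.null(res$events)) paths <- c(paths, wr(res$events, "events.tsv"))
    if (!is.null(res$classes))
        paths <- c(paths, wr(res$classes, "classes.tsv"))
    invisible(paths)
}
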