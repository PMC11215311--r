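onehotPFM <- function(consensus, id = "X", strong = 97) {
  w <- nchar(consensus)
  counts <- matrix(1, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  cv <- strsplit(consensus, "")[[1]]
  for (j in seq_len(w)) counts[cv[j], j] <- strong
  PositionFrequencyMatrix(id, counts)
}

test_that("JASPAR read/write round trip", {
  pfms <- list(onehotPFM("ACGT", "M1"), onehotPFM("TTGACA", "M2"))
  f <- tempfile(fileext = ".jaspar")
  writeJaspar(pfms, f)
  back <- readJaspar(f)
  expect_equal(names(back), c("M1", "M2"))
  expect_equal(back$M2@counts, pfms[[2]]@counts)
})

test_that("log-odds derivation matches the closed form", {
  # uniform counts, uniform background: all-zero matrix
  u <- PositionFrequencyMatrix("u", matrix(5, 4, 3))
  expect_true(all(abs(pfmToScoring(u)@logOdds) < 1e-12))
  # column (A:4, rest 0), pseudocount 1, uniform bg: A entry log2(3.4)
  p <- PositionFrequencyMatrix("p", matrix(c(4, 0, 0, 0), 4, 1))
  sm <- pfmToScoring(p, pseudocount = 1)
  expect_equal(unname(sm@logOdds["A", 1]), log2(3.4), tolerance = 1e-12)
  expect_equal(unname(sm@logOdds["C", 1]), log2((0.25 / 5) / 0.25),
               tolerance = 1e-12)
  # random PFM against an independent recomputation
  set.seed(31)
  m <- matrix(sample(0:30, 20, TRUE), 4, 5)
  m[1, colSums(m) == 0] <- 1
  sm2 <- pfmToScoring(PositionFrequencyMatrix("r", m), pseudocount = 0.8)
  man <- log2(((m + 0.8 * 0.25) / rep(colSums(m) + 0.8, each = 4)) / 0.25)
  expect_equal(unname(sm2@logOdds), unname(man), tolerance = 1e-12)
  expect_error(pfmToScoring(p, background = c(0, .5, .25, .25)), "positive")
})

test_that("DP threshold and p-values agree with word enumeration", {
  set.seed(32)
  binWidth <- 1e-3
  for (r in 1:8) {
    w <- sample(3:5, 1)
    m <- matrix(sample(0:20, 4 * w, TRUE), 4, w)
    m[1, colSums(m) == 0] <- 1
    sm <- pfmToScoring(PositionFrequencyMatrix(paste0("m", r), m))
    words <- enumeratePwmWords(sm)
    uq <- unique(words$score)
    tails <- vapply(uq, function(s)
      sum(words$prob[words$score >= s - 1e-12]), numeric(1))
    pd <- pwmTailProbability(sm, words$score, binWidth)
    for (p in c(1e-5, 1e-3, 0.05, 1)) {
      thr <- scoreThresholdForPvalue(sm, p, binWidth)
      ok <- which(tails <= p + 1e-12)
      exthr <- if (length(ok)) min(uq[ok]) else Inf
      accDP <- pd <= p + 1e-15
      accEX <- if (is.finite(exthr)) words$score >= exthr - 1e-12
               else rep(FALSE, nrow(words))
      dis <- which(accDP != accEX)
      # disagreement allowed only within one bin of either threshold
      if (length(dis)) {
        d <- pmin(abs(words$score[dis] - thr),
                  abs(words$score[dis] - if (is.finite(exthr)) exthr else thr))
        expect_lte(max(d), binWidth + 1e-12)
      }
    }
    # p-values never below the exact tail, at most one bin beyond it
    for (s in sample(words$score, 6)) {
      ps <- pwmTailProbability(sm, s, binWidth)
      pexact <- sum(words$prob[words$score >= s - 1e-12])
      phi <- sum(words$prob[words$score >= s - binWidth])
      expect_gte(ps, pexact - 1e-12)
      expect_lte(ps, phi + 1e-12)
    }
  }
})

test_that("pCutoff = 1 admits every word", {
  sm <- pfmToScoring(onehotPFM("ACG"))
  thr <- scoreThresholdForPvalue(sm, 1)
  words <- enumeratePwmWords(sm)
  expect_true(all(words$score >= thr - 5e-4 - 1e-12))
})

test_that("scanning finds planted sites on both strands, monotonically", {
  cons <- "ACGTTGCAATCG"
  sm <- pfmToScoring(onehotPFM(cons))
  set.seed(33)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  region <- paste0(substr(bg, 1, 100), cons, substr(bg, 113, 400))
  h <- scanRegion(region, sm, 1e-5)
  expect_true(any(h$offset == 101 & h$strand == "+"))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(region)))
  h2 <- scanRegion(rc, sm, 1e-5)
  L <- nchar(region); w <- nchar(cons)
  expect_true(any(h2$offset == L - 101 - w + 2 & h2$strand == "-"))
  # lowering the cutoff never adds hits
  expect_lte(nrow(scanRegion(region, sm, 1e-7)), nrow(h))
  # windows containing N are skipped
  regionN <- paste0(substr(region, 1, 104), "N", substr(region, 106, L))
  hN <- scanRegion(regionN, sm, 1e-5)
  expect_false(any(hN$offset == 101 & hN$strand == "+"))
})

test_that("upstream region arithmetic, clipping and strand", {
  # plus strand: TSS at 6001, start codon at 6101, flank 5000 -> 1001..6100
  g <- toyGenome(16000, seed = 34)
  ts <- mkTS(mkTx("t", 6001, 9000, gene = "gp"))
  orfs <- list(t = list(start = 100L, end = 400L, protein = "X",
                        cds = data.frame(start = 6101, end = 6400)))
  up <- extractUpstream(ts, g, orfs, flank = 5000)
  expect_equal(up$start, 1001)
  expect_equal(up$end, 6100)
  expect_equal(nchar(up$sequence), 5100)
  expect_equal(up$sequence,
               as.character(Biostrings::subseq(g[["c1"]], 1001, 6100)))
  # clipped at the chromosome start
  ts2 <- mkTS(mkTx("t", 801, 3000, gene = "gp"))
  orfs2 <- list(t = list(start = 100L, end = 400L, protein = "X",
                         cds = data.frame(start = 901, end = 1200)))
  expect_warning(up2 <- extractUpstream(ts2, g, orfs2, flank = 5000),
                 "clipped")
  expect_equal(up2$start, 1)
  expect_equal(up2$end, 900)
  # minus strand mirror: sequence is reverse-complemented
  tsm <- mkTS(mkTx("t", 6001, 9000, strand = "-", gene = "gm"))
  orfsm <- list(t = list(start = 100L, end = 400L, protein = "X",
                         cds = data.frame(start = 8601, end = 8900)))
  upm <- extractUpstream(tsm, g, orfsm, flank = 5000)
  expect_equal(upm$start, 8901)
  expect_equal(upm$end, 14000)
  expect_equal(upm$sequence, as.character(Biostrings::reverseComplement(
    Biostrings::subseq(g[["c1"]], 8901, 14000))))
  # longest isoform without an ORF: gene skipped with warning
  expect_warning(none <- extractUpstream(ts, g, list(t = NULL)), "no ORF")
  expect_equal(nrow(none), 0L)
})

test_that("the longest isoform is selected for the upstream region", {
  ts <- mkTS(mkTx("short", 6001, 7000, gene = "g"),
             mkTx("long", c(5501, 6501), c(6300, 7500), gene = "g"))
  g <- toyGenome(12000, seed = 35)
  orfs <- list(short = list(cds = data.frame(start = 6101, end = 6400)),
               long = list(cds = data.frame(start = 5601, end = 5900)))
  up <- extractUpstream(ts, g, orfs, flank = 2000)
  expect_equal(up$isoform_id, "long")
  expect_equal(up$start, 3501)
  expect_equal(up$end, 5600)
})

test_that("TF candidates are filtered by strict TPM > 20 in either sex", {
  hits <- data.frame(motif_id = c("m1", "m1", "m2", "m3", "m4"))
  tf <- data.frame(motif_id = c("m1", "m2", "m3"),
                   tf_gene_id = c("tf1", "tf2", "tf3"),
                   tpm_female = c(35, 10, 20), tpm_male = c(2, 10, 20))
  expect_warning(out <- filterTFCandidates(hits, tf), "m4")
  expect_equal(out$tf_gene_id, "tf1")       # 35 > 20 in females
  expect_equal(out$n_hits, 2L)              # m2: 10/10; m3: boundary 20 drops
})
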