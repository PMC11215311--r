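# reference used by the category examples: one locus, two multi-exon
# transcripts, plus a mono-exon gene elsewhere
refSet <- function() {
  mkTS(
    mkTx("r1", c(1, 201, 401), c(100, 300, 500), gene = "gA"),
    mkTx("r2", c(1, 201, 601), c(100, 500, 700), gene = "gA"),
    mkTx("mono", 5001, 5400, gene = "gM"))
}

test_that("FSM: identical junction chain, terminal ends free", {
  q <- mkTS(mkTx("q", c(21, 201, 401), c(100, 300, 480), gene = "q"))
  call <- classifyTranscripts(q, refSet())
  expect_equal(call$category, "FSM")
  expect_equal(call$matched_reference_id, "r1")
  expect_equal(call$novel_junction_count, 0L)
})

test_that("ISM: consecutive proper sub-chain (5' truncation)", {
  q <- mkTS(mkTx("q", c(221, 401), c(300, 500), gene = "q"))
  call <- classifyTranscripts(q, refSet())
  expect_equal(call$category, "ISM")
  expect_equal(call$matched_reference_id, "r1")
})

test_that("NIC: new combination of annotated sites", {
  # reference junctions: r1 has (100,201),(300,401); r2 has (100,201),(500,601)
  # query combines (100,201),(300,401),(500,601): all sites known, new chain
  ref <- mkTS(
    mkTx("r1", c(1, 201, 401), c(100, 300, 500), gene = "gA"),
    mkTx("r2", c(1, 201, 601), c(100, 500, 700), gene = "gA"))
  q <- mkTS(mkTx("q", c(1, 201, 401, 601), c(100, 300, 500, 700), gene = "q"))
  call <- classifyTranscripts(q, ref)
  expect_equal(call$category, "NIC")
  oracle <- bruteForceClassify(q, ref)
  expect_equal(oracle$category, "NIC")
})

test_that("NNC: at least one unannotated splice site", {
  q <- mkTS(mkTx("q", c(1, 251), c(100, 300), gene = "q"))  # acceptor 251 new
  call <- classifyTranscripts(q, refSet())
  expect_equal(call$category, "NNC")
  expect_gte(call$novel_junction_count, 1L)
})

test_that("Antisense, Genic, Intergenic and mono-exon FSM", {
  ref <- refSet()
  anti <- classifyTranscripts(
    mkTS(mkTx("q", 11, 90, strand = "-", gene = "q")), ref)
  expect_equal(anti$category, "Antisense")
  genic <- classifyTranscripts(mkTS(mkTx("q", 121, 180, gene = "q")), ref)
  expect_equal(genic$category, "Genic")
  inter <- classifyTranscripts(mkTS(mkTx("q", 9001, 9100, gene = "q")), ref)
  expect_equal(inter$category, "Intergenic")
  monoF <- classifyTranscripts(mkTS(mkTx("q", 5101, 5200, gene = "q")), ref)
  expect_equal(monoF$category, "FSM")
  expect_equal(monoF$matched_reference_id, "mono")
})

test_that("Fusion precedes other categories for locus-bridging queries", {
  ref <- mkTS(mkTx("r1", c(1, 201), c(100, 300), gene = "gA"),
              mkTx("r2", c(9001, 9201), c(9100, 9300), gene = "gB"))
  q <- mkTS(mkTx("q", c(201, 9001), c(300, 9100), gene = "q"))
  expect_equal(classifyTranscripts(q, ref)$category, "Fusion")
})

test_that("empty reference warns and yields Intergenic", {
  empty <- refSet()[integer(0)]
  q <- mkTS(mkTx("q", c(1, 201), c(100, 300), gene = "q"))
  expect_warning(call <- classifyTranscripts(q, empty), "Intergenic")
  expect_equal(call$category, "Intergenic")
})

test_that("every reference transcript self-classifies as FSM", {
  ref <- simulateClassificationCases(25, seed = 2)$reference
  call <- classifyTranscripts(ref, ref)
  expect_true(all(call$category == "FSM"))
})

test_that("adding reference transcripts never demotes an FSM call", {
  ref <- refSet()
  q <- mkTS(mkTx("q", c(1, 201, 401), c(100, 300, 500), gene = "q"))
  expect_equal(classifyTranscripts(q, ref["r1"])$category, "FSM")
  expect_equal(classifyTranscripts(q, ref)$category, "FSM")
  wider <- mkTS(mkTx("r1", c(1, 201, 401), c(100, 300, 500), gene = "gA"),
                mkTx("r2", c(1, 201, 601), c(100, 500, 700), gene = "gA"),
                mkTx("r3", c(1, 151, 401), c(100, 300, 520), gene = "gA"))
  expect_equal(classifyTranscripts(q, wider)$category, "FSM")
})

test_that("classifier matches the brute-force oracle on random loci", {
  cc <- simulateClassificationCases(60, seed = 31)
  a <- classifyTranscripts(cc$query, cc$reference)
  b <- bruteForceClassify(cc$query, cc$reference)
  expect_equal(a$category, b$category)
  expect_equal(a$novel_junction_count, b$novel_junction_count)
})

test_that("artifact filter: canonical motifs and novel-junction coverage", {
  calls <- data.frame(transcript_id = c("nnc", "fsm", "low"),
                      category = c("NNC", "FSM", "NNC"),
                      matched_reference_id = NA, novel_junction_count = 1L)
  support <- data.frame(
    transcript_id = c("nnc", "nnc", "fsm", "low"),
    chrom = "c1", strand = "+",
    donor = c(100, 300, 100, 100), acceptor = c(201, 401, 201, 221),
    motif = c("GTAG", "GCAG", "CTAC", "GTAG"),
    coverage = c(5L, 7L, 0L, 2L),
    is_novel = c(TRUE, TRUE, FALSE, TRUE))
  out <- filterArtifacts(calls, support, minCov = 3)
  expect_true(out$retained[out$transcript_id == "nnc"])   # cov 5,7 >= 3
  expect_true(out$retained[out$transcript_id == "fsm"])   # category exempt
  expect_false(out$retained[out$transcript_id == "low"])  # cov 2 < 3

  nc <- support
  nc$motif[1] <- "CTAC"  # non-canonical as oriented
  out2 <- filterArtifacts(calls, nc, minCov = 3)
  expect_false(out2$retained[out2$transcript_id == "nnc"])

  miss <- support
  miss$coverage[1] <- NA
  expect_error(filterArtifacts(calls, miss, minCov = 3), "support")
})

test_that("junction motifs are read strand-aware from the genome", {
  # genome with GT..AG intron on the plus strand at 101..200
  chr <- paste0(paste(rep("A", 100), collapse = ""), "GT",
                paste(rep("C", 96), collapse = ""), "AG",
                paste(rep("A", 100), collapse = ""))
  g <- Biostrings::DNAStringSet(c(c1 = chr))
  plus <- mkTS(mkTx("p", c(1, 201), c(100, 300), strand = "+"))
  ref <- mkTS(mkTx("r", c(1, 201), c(100, 300), strand = "+", gene = "gr"))
  cov <- data.frame(chrom = "c1", strand = "+", donor = 100, acceptor = 201,
                    coverage = 9L)
  sup <- junctionSupport(plus, ref, g, cov)
  expect_equal(sup$motif, "GTAG")
  expect_false(sup$is_novel)
  expect_equal(sup$coverage, 9L)
  # minus strand: the same genomic intron read as CT..AC is canonical GT-AG
  chr2 <- paste0(paste(rep("A", 100), collapse = ""), "CT",
                 paste(rep("C", 96), collapse = ""), "AC",
                 paste(rep("A", 100), collapse = ""))
  g2 <- Biostrings::DNAStringSet(c(c1 = chr2))
  minus <- mkTS(mkTx("m", c(1, 201), c(100, 300), strand = "-"))
  sup2 <- junctionSupport(minus, ref, g2, cov[0, ])
  expect_equal(sup2$motif, "GTAG")
  expect_true(sup2$is_novel)
})

test_that("reconstruction status: full, partial, fail", {
  iso <- mkTS(mkTx("i", c(1, 201, 401), c(100, 300, 500), gene = "gi"))
  rna <- mkTS(
    mkTx("full", c(11, 201, 401), c(100, 300, 480), gene = "r1"),
    mkTx("part", c(221, 401), c(300, 500), gene = "r2"),
    mkTx("bad", c(1, 251, 401), c(100, 300, 500), gene = "r3"))
  expect_equal(reconstructionStatus(iso, rna["full"])$status, "full")
  expect_equal(reconstructionStatus(iso, rna["part"])$status, "partial")
  expect_equal(reconstructionStatus(iso, rna["bad"])$status, "fail")
  # candidate order cannot change the status
  expect_equal(reconstructionStatus(iso, rna)$status, "full")
  expect_equal(reconstructionStatus(iso, rna[c(3, 2, 1)])$status, "full")
})

test_that("category tally fractions sum to one", {
  calls <- data.frame(transcript_id = letters[1:8], category = c(
    "FSM", "ISM", "NIC", "NNC", "Antisense", "Genic", "Intergenic", "Fusion"))
  tal <- categoryTally(calls)
  expect_equal(sum(tal$fraction), 1)
  expect_true(all(tal$fraction == 0.125))
  expect_equal(nrow(categoryTally(calls[0, ])), 0L)
})
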