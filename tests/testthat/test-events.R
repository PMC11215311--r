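test_that("identical exon chains yield zero events", {
  a <- mkTS(mkTx("a", c(1, 201), c(100, 300)))
  b <- mkTS(mkTx("b", c(1, 201), c(100, 300)))
  ev <- annotatePair(a, b)
  expect_equal(nrow(ev), 0L)
  expect_true(attr(ev, "comparable"))
})

test_that("different chromosome or strand is a validation error", {
  a <- mkTS(mkTx("a", 1, 100))
  b <- mkTS(mkTx("b", 1, 100, strand = "-"))
  expect_error(annotatePair(a, b), "strand")
  expect_error(annotatePair(a, mkTS(mkTx("b", 1, 100, chrom = "c2"))),
               "chromosome")
})

test_that("exon skipping: internal exon absent from the partner", {
  a <- mkTS(mkTx("a", c(1, 201, 401), c(100, 300, 500)))
  b <- mkTS(mkTx("b", c(1, 401), c(100, 500)))
  ev <- annotatePair(a, b)
  expect_equal(ev$event_type, "ES")
  expect_equal(c(ev$region_start, ev$region_end), c(201, 300))
  expect_equal(ev$owner, "a")
})

test_that("intron retention: one exon spans the partner's intron", {
  a <- mkTS(mkTx("a", 101, 400))                      # [100,400) 0-based
  b <- mkTS(mkTx("b", c(101, 301), c(200, 400)))      # [100,200)+[300,400)
  ev <- annotatePair(a, b)
  expect_equal(ev$event_type, "IR")
  expect_equal(c(ev$region_start, ev$region_end), c(201, 300))
})

test_that("A5 versus ATSS disambiguation at first exons", {
  # same start, longer donor -> A5
  a <- mkTS(mkTx("a", c(1, 201), c(100, 300)))
  b <- mkTS(mkTx("b", c(1, 201), c(180, 300)))
  expect_equal(annotatePair(a, b)$event_type, "A5")
  # different starts AND different donors, no shared upstream exon -> ATSS
  a2 <- mkTS(mkTx("a2", c(1, 201), c(100, 300)))
  b2 <- mkTS(mkTx("b2", c(151, 201), c(180, 300)))
  ev <- annotatePair(a2, b2)
  expect_true(all(ev$event_type == "ATSS"))
  # symmetric at the 3' end: A3 for shared-boundary acceptor shift
  a3 <- mkTS(mkTx("a3", c(1, 201), c(100, 300)))
  b3 <- mkTS(mkTx("b3", c(1, 151), c(100, 300)))
  expect_equal(annotatePair(a3, b3)$event_type, "A3")
})

test_that("mutually exclusive exons merge two opposite skips", {
  a <- mkTS(mkTx("a", c(1, 301, 601), c(100, 350, 700)))
  b <- mkTS(mkTx("b", c(1, 401, 601), c(100, 450, 700)))
  ev <- annotatePair(a, b)
  expect_equal(ev$event_type, "MES")
  expect_equal(ev$regions, "301-350;401-450")
})

test_that("pairs sharing no splice site with end differences are incomparable", {
  a <- mkTS(mkTx("a", c(1, 201), c(100, 300)))
  b <- mkTS(mkTx("b", c(1001, 1201), c(1100, 1300)))
  ev <- annotatePair(a, b)
  expect_equal(nrow(ev), 0L)
  expect_false(attr(ev, "comparable"))
  # but a pure IR difference without shared splice sites stays annotatable
  ir <- annotatePair(mkTS(mkTx("x", 101, 400)),
                     mkTS(mkTx("y", c(101, 301), c(200, 400))))
  expect_true(attr(ir, "comparable"))
  expect_equal(ir$event_type, "IR")
})

test_that("annotatePair is symmetric in its arguments", {
  ts <- enumeratePairGrid(c(5, 9, 14, 20, 27, 33), maxExons = 3)
  ids <- transcriptIds(ts)
  set.seed(4)
  pick <- do.call(rbind, replicate(60, sample(ids, 2), simplify = FALSE))
  fwd <- annotatePairs(ts, data.frame(isoform_a = pick[, 1],
                                      isoform_b = pick[, 2]),
                       simplify = FALSE)
  rev <- annotatePairs(ts, data.frame(isoform_a = pick[, 2],
                                      isoform_b = pick[, 1]),
                       simplify = FALSE)
  for (k in seq_along(fwd)) {
    ab <- fwd[[k]]; ba <- rev[[k]]
    expect_identical(attr(ab, "comparable"), attr(ba, "comparable"))
    expect_equal(ab$event_type, ba$event_type)
    expect_equal(ab$region_start, ba$region_start)
    # owners swap roles
    expect_equal(ab$owner == "a", ba$owner == "b")
  }
})

test_that("flipping the strand swaps ATSS/ATTS and A5/A3", {
  grid <- c(5, 9, 14, 20, 27, 33)
  tsP <- enumeratePairGrid(grid, maxExons = 3, strand = "+")
  tsM <- enumeratePairGrid(grid, maxExons = 3, strand = "-")
  ids <- transcriptIds(tsP)
  set.seed(5)
  pick <- do.call(rbind, replicate(80, sample(ids, 2), simplify = FALSE))
  pairs <- data.frame(isoform_a = pick[, 1], isoform_b = pick[, 2])
  evP <- annotatePairs(tsP, pairs, simplify = FALSE)
  evM <- annotatePairs(tsM, pairs, simplify = FALSE)
  for (k in seq_along(evP)) {
    expect_identical(attr(evP[[k]], "comparable"),
                     attr(evM[[k]], "comparable"))
    expect_equal(unname(EVENT_SWAP[evP[[k]]$event_type]),
                 evM[[k]]$event_type)
  }
})

test_that("the reverse-complement view leaves event types unchanged", {
  ts <- enumeratePairGrid(c(5, 9, 14, 20, 27, 33), maxExons = 3)
  ids <- transcriptIds(ts)
  refl <- reflectTranscripts(ts, mirror = 100L)
  set.seed(6)
  pick <- do.call(rbind, replicate(60, sample(ids, 2), simplify = FALSE))
  pairs <- data.frame(isoform_a = pick[, 1], isoform_b = pick[, 2])
  evs <- annotatePairs(ts, pairs, simplify = FALSE)
  rvs <- annotatePairs(refl, pairs, simplify = FALSE)
  for (k in seq_along(evs)) {
    expect_identical(attr(evs[[k]], "comparable"),
                     attr(rvs[[k]], "comparable"))
    expect_equal(sort(evs[[k]]$event_type), sort(rvs[[k]]$event_type))
  }
})

test_that("annotator matches the per-base oracle on a small grid", {
  for (strand in c("+", "-")) {
    ts <- enumeratePairGrid(c(5, 9, 14, 15, 27, 33), maxExons = 3,
                            strand = strand)
    ids <- transcriptIds(ts)
    cmb <- combn(ids, 2)
    pairs <- data.frame(isoform_a = cmb[1, ], isoform_b = cmb[2, ])
    orc <- bruteForcePairs(ts, pairs)
    evs <- annotatePairs(ts, pairs, simplify = FALSE)
    ok <- vapply(seq_len(nrow(pairs)), function(k)
      sameEvents(evs[[k]], orc[[k]]), logical(1))
    expect_true(all(ok))
  }
})

test_that("annotateLocus covers all pairs and flags incomparable ones", {
  loc <- mkTS(mkTx("t1", c(1, 201, 401), c(100, 300, 500), gene = "g"),
              mkTx("t2", c(1, 401), c(100, 500), gene = "g"),
              mkTx("t3", c(1, 201, 401), c(100, 300, 560), gene = "g"))
  ev <- annotateLocus(loc)
  expect_true(all(c("ES", "ATTS") %in% ev$event_type))
  expect_equal(length(attr(ev, "incomparable_pairs")), 0L)
})

test_that("in_coding_region flags events intersecting either CDS", {
  a <- mkTS(mkTx("a", c(1, 201, 401), c(100, 300, 500)))
  b <- mkTS(mkTx("b", c(1, 401), c(100, 500)))
  cdsIn <- data.frame(start = c(50, 201), end = c(100, 250))
  cdsOut <- data.frame(start = 450, end = 490)
  evIn <- annotatePair(a, b, cdsA = cdsIn, cdsB = NULL)
  expect_true(evIn$in_coding_region)
  evOut <- annotatePair(a, b, cdsA = cdsOut, cdsB = cdsOut)
  expect_false(evOut$in_coding_region)
})

test_that("event type distribution sums to one and splits by bias", {
  ev <- data.frame(gene_id = "g", isoform_a = "f", isoform_b = "m",
                   event_type = c("ATSS", "ATSS", "ATTS", "ES"),
                   region_start = 1:4, region_end = 2:5,
                   regions = "x", owner = c("a", "a", "b", "b"),
                   in_coding_region = NA)
  d <- eventTypeDistribution(ev, biasLabels = c(f = "female", m = "male"))
  expect_equal(sum(d$fraction), 1)
  expect_equal(d$count[d$event_type == "ATSS"], 2L)
  expect_equal(d$count_female[d$event_type == "ATSS"], 2L)
  expect_equal(d$count_male[d$event_type == "ATTS"], 1L)
  expect_equal(nrow(eventTypeDistribution(ev[0, ])), 0L)
})
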