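# small builders shared across test files

# one transcript from paired vectors (1-based inclusive coordinates)
mkTx <- function(id, starts, ends, strand = "+", chrom = "c1", gene = "g1") {
  data.frame(chrom = chrom, start = starts, end = ends, strand = strand,
             transcript_id = id, gene_id = gene)
}

mkTS <- function(...) TranscriptSet(do.call(rbind, list(...)))

# deterministic uniform toy genome
toyGenome <- function(len = 2000, seed = 1, chroms = "c1") {
  set.seed(seed)
  s <- vapply(chroms, function(chr)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  g <- Biostrings::DNAStringSet(s)
  names(g) <- chroms
  g
}

# random valid transcript models (non-abutting exons)
randomModels <- function(n, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    pos <- cumsum(sample(30:400, 2 * k))
    mkTx(sprintf("t%05d", i),
         starts = pos[seq(1, 2 * k, 2)], ends = pos[seq(2, 2 * k, 2)],
         strand = sample(c("+", "-"), 1),
         chrom = paste0("c", sample(1:4, 1)),
         gene = sprintf("g%04d", i))
  })
  TranscriptSet(do.call(rbind, rows))
}

EVENT_SWAP <- c(A3 = "A5", A5 = "A3", ATSS = "ATTS", ATTS = "ATSS",
                ES = "ES", IR = "IR", MES = "MES")

# compare an annotatePair table against an oracle table
sameEvents <- function(ev, orc) {
  identical(attr(ev, "comparable"), attr(orc, "comparable")) &&
    nrow(ev) == nrow(orc) &&
    all(ev$event_type == orc$event_type) &&
    all(ev$region_start == orc$region_start) &&
    all(ev$region_end == orc$region_end) &&
    all(ev$owner == orc$owner)
}
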