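mkIE <- function(counts, geneId, len, nF = 3, nM = 3) {
  IsoformExperiment(counts, geneId, len,
                    sex = rep(c("Female", "Male"), c(nF, nM)))
}

test_that("TPM follows the closed form and columns sum to 1e6", {
  cnt <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- computeTPM(cnt, effectiveLength = c(100, 200))
  expect_equal(unname(tpm[, 1]), c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  one <- computeTPM(matrix(5, 1, 1, dimnames = list("a", "s")),
                    effectiveLength = 300)
  expect_equal(unname(one[1, 1]), 1e6)
  set.seed(21)
  cnt2 <- matrix(rpois(60, 40), 10, 6,
                 dimnames = list(paste0("i", 1:10), paste0("s", 1:6)))
  tpm2 <- computeTPM(cnt2, effectiveLength = sample(200:900, 10))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 6), tolerance = 1e-6)
  z <- cnt2; z[, 3] <- 0
  expect_warning(tz <- computeTPM(z, effectiveLength = rep(500, 10)),
                 "all-zero")
  expect_true(all(tz[, 3] == 0))
})

test_that("isoform fractions sum to one per gene and sample", {
  set.seed(22)
  gene <- rep(paste0("g", 1:30), each = 2)
  cnt <- matrix(rpois(60 * 6, 50), 60, 6,
                dimnames = list(paste0("i", 1:60), paste0("s", 1:6)))
  tpm <- computeTPM(cnt, effectiveLength = sample(300:900, 60))
  ifm <- isoformFraction(tpm, gene)
  sums <- rowsum(ifm, gene)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  # zero-expression gene: undefined fractions
  cnt[1:2, ] <- 0
  tpm0 <- computeTPM(cnt, effectiveLength = rep(500, 60))
  if0 <- isoformFraction(tpm0, gene)
  expect_true(all(is.na(if0[1:2, ])))
})

test_that("two-isoform genes have exactly opposite dIFs", {
  set.seed(23)
  cnt <- matrix(rpois(2 * 6, 80), 2, 6,
                dimnames = list(c("a", "b"), paste0("s", 1:6)))
  ie <- mkIE(cnt, c("g", "g"), c(500, 700))
  u <- testIsoformUsage(ie, method = "welch")
  expect_equal(u$dIF[1], -u$dIF[2], tolerance = 1e-12)
})

test_that("identical usage in both sexes gives permutation p = 1", {
  cnt <- matrix(rep(c(30, 70), 6), 2, 6,
                dimnames = list(c("a", "b"), paste0("s", 1:6)))
  ie <- mkIE(cnt, c("g", "g"), c(100, 100))
  u <- testIsoformUsage(ie, method = "permutation")
  expect_equal(u$dIF, c(0, 0))
  expect_equal(u$p_value, c(1, 1))
})

test_that("swapping condition labels negates dIF and keeps p", {
  set.seed(24)
  cnt <- matrix(rpois(4 * 8, 60), 4, 8,
                dimnames = list(paste0("i", 1:4), paste0("s", 1:8)))
  gene <- c("g1", "g1", "g2", "g2")
  ie <- IsoformExperiment(cnt, gene, rep(400, 4),
                          sex = rep(c("Female", "Male"), each = 4))
  ieSwap <- IsoformExperiment(cnt, gene, rep(400, 4),
                              sex = rep(c("Male", "Female"), each = 4))
  for (m in c("welch", "permutation")) {
    u <- testIsoformUsage(ie, method = m)
    v <- testIsoformUsage(ieSwap, method = m)
    expect_equal(u$dIF, -v$dIF, tolerance = 1e-12)
    expect_equal(u$p_value, v$p_value, tolerance = 1e-12)
  }
})

test_that("Welch mode agrees with stats::t.test", {
  set.seed(25)
  cnt <- matrix(rpois(2 * 10, 100) + 1, 2, 10,
                dimnames = list(c("a", "b"), paste0("s", 1:10)))
  ie <- mkIE(cnt, c("g", "g"), c(500, 800), nF = 5, nM = 5)
  u <- testIsoformUsage(ie, method = "welch")
  tpm <- computeTPM(ie)
  ifm <- isoformFraction(tpm, geneIds(ie))
  tt <- t.test(ifm[1, 1:5], ifm[1, 6:10])
  expect_equal(u$p_value[1], tt$p.value, tolerance = 1e-9)
})

test_that("single-isoform genes are not tested", {
  set.seed(26)
  cnt <- matrix(rpois(3 * 6, 50), 3, 6,
                dimnames = list(c("a", "b", "solo"), paste0("s", 1:6)))
  ie <- mkIE(cnt, c("g1", "g1", "g2"), rep(500, 3))
  u <- testIsoformUsage(ie, method = "permutation")
  expect_true(is.na(u$p_value[u$isoform_id == "solo"]))
  expect_false(anyNA(u$p_value[u$gene_id == "g1"]))
})

test_that("sex-biased calls respect all three thresholds", {
  base <- data.frame(isoform_id = "i", gene_id = "g", IF_female = .6,
                     IF_male = .35, dIF = .25, p_value = .001,
                     q_value = .01, mean_TPM_female = 30, mean_TPM_male = 12)
  expect_equal(callSexBiased(base)$bias, "female")
  lowTPM <- base; lowTPM$mean_TPM_male <- 0.5
  expect_equal(callSexBiased(lowTPM)$bias, "none")
  smallDif <- base; smallDif$dIF <- 0.09; smallDif$q_value <- 1e-6
  expect_equal(callSexBiased(smallDif)$bias, "none")
  male <- base; male$dIF <- -0.25
  expect_equal(callSexBiased(male)$bias, "male")
  # boundaries are strict
  edge <- base; edge$dIF <- 0.1
  expect_equal(callSexBiased(edge)$bias, "none")
  edge2 <- base; edge2$q_value <- 0.05
  expect_equal(callSexBiased(edge2)$bias, "none")
})

test_that("switch genes need opposite-direction biased isoforms", {
  u <- data.frame(isoform_id = c("a", "b", "c", "d"),
                  gene_id = c("g1", "g1", "g2", "g2"),
                  IF_female = 0, IF_male = 0,
                  dIF = c(0.5, -0.5, 0.5, 0.2),
                  p_value = 0.001, q_value = 0.001,
                  mean_TPM_female = 30, mean_TPM_male = 30)
  u$bias <- c("female", "male", "female", "female")
  sw <- callSwitchGenes(u)
  expect_true(sw$is_switch[sw$gene_id == "g1"])
  expect_false(sw$is_switch[sw$gene_id == "g2"])
  expect_equal(sw$female_isoform[sw$gene_id == "g1"], "a")
  expect_equal(sw$male_isoform[sw$gene_id == "g1"], "b")
})

test_that("key-gene filter applies TPM, coding and ATSS/ATTS rules", {
  usage <- data.frame(isoform_id = c("f", "m"), gene_id = "g",
                      IF_female = c(.7, .3), IF_male = c(.3, .7),
                      dIF = c(.4, -.4), p_value = 1e-4, q_value = 1e-3,
                      mean_TPM_female = c(40, 15), mean_TPM_male = c(15, 40),
                      bias = c("female", "male"))
  switches <- callSwitchGenes(usage)
  orfs <- list(
    f = list(start = 0, end = 99, protein = "AAA",
             cds = data.frame(start = 101, end = 200)),
    m = list(start = 0, end = 99, protein = "BBB",
             cds = data.frame(start = 151, end = 250)))
  evATSS <- data.frame(gene_id = "g", isoform_a = "f", isoform_b = "m",
                       event_type = "ATSS", region_start = 120,
                       region_end = 180, regions = "120-180", owner = "a",
                       in_coding_region = TRUE)
  out <- keyGeneFilter(switches, usage, orfs, evATSS)
  expect_true(out$is_key)
  # TPM below 20 in both sexes for one biased isoform: not key
  lu <- usage; lu$mean_TPM_female <- c(12, 8); lu$mean_TPM_male <- c(8, 12)
  expect_false(keyGeneFilter(callSwitchGenes(lu), lu, orfs, evATSS)$is_key)
  # only a non-coding ATTS difference: not key
  evUTR <- evATSS; evUTR$event_type <- "ATTS"; evUTR$in_coding_region <- FALSE
  expect_false(keyGeneFilter(switches, usage, orfs, evUTR)$is_key)
  # identical coding regions: not key
  orfsSame <- orfs; orfsSame$m <- orfs$f
  expect_false(keyGeneFilter(switches, usage, orfsSame, evATSS)$is_key)
})

test_that("length classes and dIF ranking", {
  switches <- data.frame(gene_id = c("g1", "g2"),
                         n_female_biased = 1, n_male_biased = 1,
                         is_switch = TRUE,
                         female_isoform = c("f1", "f2"),
                         male_isoform = c("m1", "m2"),
                         female_dIF = c(0.6, 0.3), male_dIF = c(-0.6, -0.3),
                         is_key = TRUE)
  lens <- c(f1 = 2400, m1 = 1200, f2 = 900, m2 = 1800)
  cl <- categorizeAndRank(switches, lens)
  expect_equal(cl$male_length_class, c("shorter", "longer"))
  expect_equal(cl$female_length_class, c("longer", "shorter"))
  # g1 and g2 are in different classes, each rank 1
  expect_equal(cl$male_rank, c(1L, 1L))
  # same class ranking by descending |dIF|
  switches2 <- switches
  switches2$male_isoform <- c("m1", "m3")
  lens2 <- c(lens, m3 = 400)
  cl2 <- categorizeAndRank(switches2, lens2)
  expect_equal(cl2$male_rank, c(1L, 2L))
  # equal lengths -> n/a with warning
  eq <- switches[1, ]; lens3 <- c(f1 = 1000, m1 = 1000)
  expect_warning(cl3 <- categorizeAndRank(eq, lens3), "equal")
  expect_equal(cl3$male_length_class, "n/a")
})

test_that("planted switches are recovered on a small simulation", {
  cfg <- simulationConfig(seed = 99, nGenes = 150, switchFraction = 0.2)
  sim <- simulateDataset(cfg, sequences = FALSE)
  u <- callSexBiased(testIsoformUsage(sim$ie, method = "permutation"))
  sw <- callSwitchGenes(u)
  m <- merge(sw, sim$truth$switches, by = "gene_id")
  recall <- with(m, sum(is_switch.x & is_switch.y) / sum(is_switch.y))
  expect_gte(recall, 0.8)
  expect_equal(with(m, sum(is_switch.x & !is_switch.y)), 0)
  # empirical dIF tracks the planted effect for detected switch isoforms
  tru <- sim$truth$usage
  mm <- merge(u, tru, by = "isoform_id")
  planted <- mm[abs(mm$expected_dIF) > 0, ]
  expect_lt(median(abs(planted$dIF - planted$expected_dIF)), 0.1)
})
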