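---
title: "Classifying long-read isoforms and detecting sex-biased isoform switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying long-read isoforms and detecting sex-biased isoform switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoswitch)
```

## Scope and model

`isoswitch` implements a complete desk-scale pipeline for the analysis of
alternative splicing in an insect antennal long-read (Iso-Seq style)
transcriptome, of the kind used to characterise sex-biased isoform usage in
the oriental fruit fly:

1. **Structural classification** of each long-read transcript against a
   reference annotation into eight categories (FSM, ISM, NIC, NNC,
   Antisense, Genic, Intergenic, Fusion), with canonical-splice-motif and
   junction-coverage artifact filters.
2. **Alternative-splicing event annotation** on isoform pairs into seven
   types: A3, A5, ATSS, ATTS, ES, IR, MES.
3. **Differential isoform usage** between two conditions (here: female and
   male) via the isoform fraction IF = isoform TPM / gene TPM and the
   effect size dIF = mean IF(Female) − mean IF(Male); isoform-switch and
   key-gene calling.
4. **Longest-ORF prediction** and genomic CDS mapping, used to decide
   whether a switch affects protein-coding regions.
5. **Upstream-region extraction and PWM scanning** with exact background
   p-values, to find sex-differentiation transcription-factor binding sites
   upstream of key genes.
6. A **synthetic-data generator** that produces all inputs with recorded
   ground truth, so every stage is testable end to end.

All containers are standard Bioconductor objects: transcript models are a
`GRangesList` inside the `TranscriptSet` class, counts live in an
`IsoformExperiment` (a `SummarizedExperiment`), sequences in
`DNAStringSet`s, and GTF/FASTA I/O goes through `rtracklayer` and
`Biostrings`. Coordinates are 1-based inclusive throughout, the native
GRanges convention, so GTF I/O is conversion-free.

## Structural classification

A transcript's *junction chain* is its ordered list of (donor, acceptor)
positions. Categories are assigned by precedence:

* **Fusion** — same-strand exonic overlap with two or more reference loci
  (multi-exon queries only); checked first so bridging transcripts are not
  mistaken for NNC.
* **FSM** — chain identical to some reference transcript; terminal exon
  start/end positions are deliberately ignored, so 5'/3' end variation does
  not break a full splice match. Mono-exon queries are FSM when contained
  within a reference mono-exon transcript's exon.
* **ISM** — proper *consecutive* sub-chain of a reference chain (any
  window, not only a prefix or suffix).
* **NIC** — every donor and acceptor individually annotated at the locus,
  but the combination is new.
* **NNC** — at least one unannotated splice site.
* **Antisense / Genic / Intergenic** — by opposite-strand exonic overlap,
  residual same-strand overlap, or no overlap.

Tie-breaks (several matching reference transcripts) prefer the longest
spliced reference, then the lexicographically smallest id — an arbitrary
but deterministic rule. The artifact filter retains a novel-category
transcript only when all its splice motifs are canonical (GT-AG, GC-AG,
AT-AC, read in transcript orientation from the genome) and every novel
junction has short-read coverage ≥ `minCov` (default 3); FSM/ISM are always
retained. An RT-switching filter is intentionally not implemented.

`bruteForceClassify()` is an independently coded reference implementation
(string enumeration of all chains and sub-chains, loop-based overlap and
site sets) used by the test suite and the acceptance script to verify the
classifier on hundreds of random loci.

## Event annotation on isoform pairs

Events are defined on isoform *pairs* (e.g. the up/down pair of a switch),
not against a master transcript. The difference between two exon chains is
decomposed into maximal genomic regions exonic in exactly one isoform; each
region receives exactly one type with precedence IR > ES/MES > A5/A3 >
ATSS/ATTS:

* both flanks of the region exonic in both isoforms → **IR**;
* region is a complete internal exon of one isoform inside the other's
  span → **ES**; two adjacent such regions owned by opposite isoforms with
  no shared exon between them merge into one **MES**;
* one flank shared and both isoforms splice onwards → **A5** (donor side)
  or **A3** (acceptor side), mapped through the strand;
* anything anchored at a transcript end → **ATSS**/**ATTS**.

This rule table is a stated convention: the disambiguation of A5/A3 versus
ATSS/ATTS at first/last exons is not uniquely defined in the literature. We
resolve it by whether *both* isoforms continue splicing at the boundary
(then it is a donor/acceptor shift) or either terminates (then it is an end
difference). Pairs that share no splice site and differ at their ends are
reported *incomparable* and excluded from tallies; a pure intron-retention
difference (e.g. a mono-exon isoform spanning a spliced partner with
identical ends) does not require a shared splice site.

The oracle `bruteForcePairEvents()` re-implements the table on per-base
logical vectors and handles the minus strand by mirroring coordinates onto
the plus strand, so strand covariance is structural. The test suite and
acceptance script compare the two implementations exhaustively on every
pair of transcripts drawn from an 8-point boundary grid (127 transcripts,
8001 pairs, both strands) — all configurations of up to 4 exons over that
grid, including single-base exons and introns. Flipping the strand label of
a pair swaps ATSS↔ATTS and A5↔A3 in every grid case; the MES merge is
greedy in genomic order, so only event *types* (not the pairing of regions)
are guaranteed invariant under full reverse-complement reflection.

## Differential isoform usage and switching

TPM is computed as `1e6 * (c/l) / sum(c/l)` per sample with effective
length = spliced length; IF = isoform TPM / gene TPM (undefined when the
gene TPM is 0). The effect size is dIF = mean IF(Female) − mean IF(Male).
Two tests on per-replicate IF are provided:

* **Welch's t-test** (default `"welch"`): closed-form, fast; degenerate
  zero-variance rows fall back to p = 1 (no difference) or 0.
* **Permutation test** (`"permutation"`): the absolute difference in mean
  IF under condition-label permutations. With n ≤ ~10 per side all
  `choose(n, nF)` assignments are enumerated exactly (924 at 6 + 6), so the
  mode needs no RNG and p ≥ 1/K; otherwise random assignments are drawn
  under a user seed with the add-one estimator.

q-values are Benjamini–Hochberg across all tested isoforms genome-wide.
Only isoforms of multi-isoform genes are tested: a single-isoform gene has
IF ≡ 1 and carries no usage information (the upstream screen in this kind
of study is restricted to multi-isoform loci for the same reason). A gene
is retained only when its TPM is positive in at least one sample.

Thresholds follow the study design: an isoform is sex-biased when
|dIF| > 0.1, q < 0.05 and mean TPM > 1 in *both* sexes (strict
inequalities; "TPM mean" is the arithmetic mean over replicates within
sex, applied per isoform). A gene switches when it has at least one female-
and one male-biased isoform. A switching gene is *key* when every biased
isoform has mean TPM > 20 in at least one sex, the top female- and
male-biased isoforms differ in protein-coding regions, and their event list
contains a coding-region ATSS or ATTS. Key genes are placed in the four
male/female × shorter/longer classes by the spliced lengths of the two top
isoforms and ranked within class by descending |dIF|.

`codingRegionsDiffer()` is deliberately strict: isoforms differ when either
the protein sequences or the genomic CDS interval sets differ, because an
ATSS can relocate the CDS without changing the protein.

## ORF calling

`longestOrf()` scans the transcript sense strand in all three frames for
ATG-initiated, stop-terminated ORFs; N-containing codons are
non-translatable barriers. Ties go to the 5'-most start. The default
minimum length is 100 nt including the stop codon — the usual default for
long-read ORF annotation — and is configurable; the brute-force maximality
oracle in the tests runs with the minimum disabled.

## PWM scanning with exact p-values

A JASPAR-style PFM is converted to a log2-odds matrix with a total
pseudocount (default 0.8) split by the background (default uniform;
region-derived backgrounds can be supplied). The score threshold for a
p-value cutoff is the smallest s with P(score(W) ≥ s) ≤ p under i.i.d.
background, computed by dynamic programming over the discretised column
score distributions. Columns are binned at `binWidth / w` (default output
bin 1e-3), so the accumulated rounding error of any word score is below
half an output bin. Tail probabilities are conservative: the query score is
lowered by this half-bin error before the tail lookup, so a word's own
probability mass is always included and the reported p-value never
undershoots the exact tail. Hits are accepted by the p-value rule
`p(score) <= pCutoff`; consequently the DP and the exhaustive 4^w
enumeration accept identical word sets except possibly for words whose
score lies within one bin of the cutoff. Both strands are
scanned at every offset, windows containing N are skipped, and overlapping
hits are all reported.

Upstream regions run from 5000 bp upstream of the TSS of the gene's
*longest* isoform to the base immediately before that isoform's start
codon, unspliced (introns in the 5' UTR are retained, since regulatory
sites can sit in them), clipped at chromosome ends, reverse-complemented
for minus-strand genes. The start codon itself is excluded. Genes whose
longest isoform has no predicted ORF are skipped with a warning.
Candidate transcription factors are kept when their antennal expression
exceeds TPM 20 in females or males (strict).

## The synthetic-data generator

`simulateDataset()` emits a genome, a reduced reference annotation (one
base isoform per gene), a long-read transcript set, a short-read
(assembled) transcript set, junction coverage, an isoform count matrix
with a sex design, a motif, and ground truth for every stage. Design
choices:

* **Structural truths are noiseless.** Extra isoforms are constructed by
  applying one AS edit to the base isoform (TSS/TTS shifts, exon skip,
  intron retention, donor/acceptor shifts, exclusive-exon swap), each
  yielding exactly one recoverable event and a known structural category
  relative to the reduced reference (TSS/TTS shifts → FSM, skips/retention
  → NIC, new sites → NNC). Statistical noise is confined to counts and
  background sequence, so classifier/annotator tests are sharp while
  inference tests are statistical.
* **Defaults are the study conditions**: 59% single-isoform loci (41%
  multi-isoform, 29.3% with 2–3 isoforms), event mix with ATSS 31% and
  ATTS 33%, reconstruction mix 24.8/29.3/45.9% full/partial/fail, 10%
  planted switches at |dIF| = 0.4, 6 replicates per sex, NB dispersion
  0.05 (Var = μ + φμ²), library size 1e6 with log-normal (sdlog = 1) gene
  abundances — a realistic bulk RNA-seq scale at which the TPM > 1 filter
  is active but not dominant.
* Counts are negative-binomial with expected counts proportional to molar
  usage × effective length, so the *TPM-scale* dIF of the planted pair is
  exactly ±0.4; usage of non-switch isoforms is identical across sexes.
* The genome is edited for consistency: every base isoform receives a
  planted ORF spanning most of its spliced length (12 nt 5' UTR, ~45 nt 3'
  UTR, no ATG in the 5' UTR), every intron of every emitted transcript
  gets canonical GT-AG dinucleotides, and motif consensi are implanted
  200–2000 bp upstream of base TSSs. TSS/TTS shifts (60–90 nt) always
  cross the CDS boundary, so ATSS/ATTS switch pairs are coding-affecting
  by construction.

What the generator does **not** emulate: read-level errors, positional
coverage bias, fragment-length effects, overlapping gene models, alternate
gene structures sharing exons between loci, non-uniform genomic base
composition, and real promoter architecture. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated model, not performance on real libraries.

## Numerical choices and problem sizes

* Exact permutation enumeration is used whenever `choose(n, nF)` ≤ 20000;
  at 6 + 6 replicates the p-value floor is 2/924 (the complete label swap
  always matches |dIF|).
* PWM DP bin width 1e-3 (score units); thresholds and p-values are exact
  to one bin.
* Welch's degenerate-variance fallback and the strict (>) thresholds on
  dIF, FDR and TPM are boundary rules fixed once and tested at the
  boundary.
* Validation sizes used by the tests and the acceptance script: 500 random
  loci for the classification oracle, the full 8-point grid (8001 pairs ×
  2 strands) for the event oracle, 1000 genes at seed-fixed conditions for
  switch recall/FDR, 1000 two-isoform genes (2000 isoforms) for null
  calibration, 20 random PFMs of width ≤ 5 for the PWM oracle, 1000 random
  models for the GTF round trip.

## Known limitations

* Locus membership comes from `gene_id` in the input GTF; no overlap-based
  regrouping is performed (matching the upstream collapse step this
  package expects), except in `sharedLoci()`.
* The Fusion/Genic/Antisense boundaries for mono-exon reads follow
  SQANTI-style conventions; the distinctions are not sharply defined in
  the field and other tools differ.
* The DEXSeq-based test used by IsoformSwitchAnalyzeR is replaced by the
  Welch/permutation tests above; the downstream thresholds act on dIF and
  FDR, not on test internals, but p-values on real overdispersed data will
  differ from DEXSeq's.
* `eventTypeDistribution()` attributes an event to the bias of the isoform
  containing the region, which is a convention (MES events are inherently
  symmetric).

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 7, nGenes = 120)
sim <- simulateDataset(cfg)

calls <- classifyTranscripts(sim$isoseq, sim$reference)
categoryTally(calls)

res <- runSwitchAnalysis(sim$isoseq, sim$genome, sim$ie, seed = 7)
subset(res$switches, is_switch)
res$classes

orfs <- predictOrfs(sim$isoseq, sim$genome)
regions <- extractUpstream(sim$isoseq, sim$genome, orfs)
hits <- scanUpstreamRegions(regions, list(pfmToScoring(sim$pfm)))
head(hits)
```
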