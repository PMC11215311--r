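# isoswitch

Alternative-splicing analysis for long-read (Iso-Seq style) insect
transcriptomes, built for studies of sex-biased isoform usage in
chemosensory tissue such as fruit-fly antennae. Given a genome, a reference
annotation, a set of collapsed long-read transcript models, a short-read
assembled transcript set, and an isoform count matrix with a female/male
design, the package:

- **classifies** each long-read transcript against the reference into the
  eight standard structural categories — FSM (full splice match), ISM
  (incomplete splice match), NIC (novel in catalog), NNC (novel not in
  catalog), Antisense, Genic, Intergenic, Fusion — and filters artifacts by
  canonical splice motifs (GT-AG/GC-AG/AT-AC) and novel-junction coverage
  (`min_cov` = 3);
- **annotates** seven alternative-splicing event types on isoform pairs:
  alternative 3'/5' splice sites (A3, A5), alternative transcription start
  and termination sites (ATSS, ATTS), exon skipping (ES), intron retention
  (IR), mutually exclusive exons (MES);
- **tests differential isoform usage** between sexes on the isoform
  fraction IF = isoform TPM / gene TPM with the effect size
  `dIF = IF(Female) − IF(Male)` (Welch or exact permutation test,
  Benjamini–Hochberg FDR), calling sex-biased isoforms at |dIF| > 0.1,
  FDR < 0.05 and mean TPM > 1 in both sexes, switch genes (one isoform
  biased each way) and **key genes** (all biased isoforms TPM > 20 in a
  sex, coding regions differing between the top female- and male-biased
  isoforms, and a coding-region ATSS/ATTS event), ranked in the four
  male/female × shorter/longer length classes by descending |dIF|;
- **predicts longest ORFs** on transcript sense strands and maps them to
  genomic CDS intervals;
- **extracts upstream regulatory regions** (5 kb upstream of the longest
  isoform's TSS down to its start codon, unspliced) and **scans them with
  JASPAR-style PWMs** at an exact background p-value cutoff (default 1e-5)
  computed by dynamic programming, filtering candidate transcription
  factors by antennal expression (TPM > 20);
- ships a **deterministic synthetic-data generator** with recorded ground
  truth for every stage, plus brute-force reference implementations
  (`bruteForceClassify`, `bruteForcePairEvents`, `enumeratePwmWords`) used
  to validate the fast paths.

Everything is standard Bioconductor machinery: `TranscriptSet` wraps a
`GRangesList`, counts live in an `IsoformExperiment`
(`SummarizedExperiment`), I/O goes through `rtracklayer` and `Biostrings`.

## Worked example

```r
library(isoswitch)

cfg <- simulationConfig(seed = 7, nGenes = 120)
sim <- simulateDataset(cfg)           # genome, GTFs, counts, truth

calls <- classifyTranscripts(sim$isoseq, sim$reference)
categoryTally(calls)
#>     category count    fraction
#> 1        FSM   170 0.735930736
#> 2        NNC    26 0.112554113
#> 3        NIC    14 0.060606061
#> 4        ISM    10 0.043290043
#> 5  Antisense     3 0.012987013
#> 6      Genic     3 0.012987013
#> 7 Intergenic     3 0.012987013
#> 8     Fusion     2 0.008658009

res <- runSwitchAnalysis(sim$isoseq, sim$genome, sim$ie, seed = 7)
subset(res$switches, is_switch)[, c(1, 5:9)]
#>     gene_id female_isoform male_isoform female_dIF   male_dIF is_key
#> 10    G0010        G0010.1      G0010.2  0.3933504 -0.3843994   TRUE
#> 57    G0057        G0057.1      G0057.2  0.3417039 -0.3417039   TRUE
#> 109   G0109        G0109.2      G0109.1  0.4115206 -0.3886033  FALSE
#> 117   G0117        G0117.2      G0117.1  0.3658455 -0.3815266  FALSE

res$classes
#>   gene_id male_length_class female_length_class   male_dIF female_dIF ...
#> 1   G0010           shorter              longer -0.3843994  0.3933504
#> 2   G0057           shorter              longer -0.3417039  0.3417039
```

The tally mirrors the planted structural truth exactly (the generator
constructs each novel category to be recoverable). Four genes carry planted
usage switches at |dIF| = 0.4; the two whose switch pair involves a
coding-region ATSS/ATTS event and clears the TPM > 20 filter are key genes,
here both "male prefers the shorter isoform / female the longer", ranked by
|dIF| within the class. The estimated dIF values sit near the planted ±0.4.

Promoter scanning on the same dataset:

```r
orfs    <- predictOrfs(sim$isoseq, sim$genome)
regions <- extractUpstream(sim$isoseq, sim$genome, orfs)
hits    <- scanUpstreamRegions(regions, list(pfmToScoring(sim$pfm)))
```

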