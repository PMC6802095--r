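# rrcna — reduced-representation copy-number analysis

`rrcna` is an R toolkit for restriction-site-anchored
reduced-representation DNA sequencing of the CUTseq family: libraries in
which genomic DNA is digested with a restriction enzyme (NlaIII `CATG`
or HindIII `AAGCTT` built in), and adapters carrying an 8-nt unique
molecular identifier (UMI) plus an 8-nt sample barcode are ligated at
the cut sites. Every read is `UMI + barcode + genomic insert`, with the
insert's 5' end at an enzyme cut coordinate; UMI counting turns reads
into single-molecule counts proportional to local DNA copy number. The
package is aimed at people designing such assays (enzyme choice),
processing their reads, and calling DNA copy-number alterations and
intratumor heterogeneity statistics from them — plus a full generative
simulator so that the entire stack is testable without external data.

## What it computes

* **Digest design**: recognition-site scans of a genome; inter-site
  distance distributions (mean ± SD, median); per-100-kb spacing
  homogeneity; site density per kb in (shifted) target regions;
  distance from points to the nearest site.
* **Simulation**: synthetic genomes, ground-truth integer copy-number
  landscapes, and FASTQ reads with per-site molecule counts
  `~ Poisson(λ · copy)` per strand, uniform UMIs, Poisson PCR
  duplicates and i.i.d. substitution errors.
* **Read processing**: prefix parsing; barcode assignment allowing ≤ 2
  mismatches (ties rejected as ambiguous); exact-match cut-site
  anchoring (±3 bp) or SAM/BAM ingestion; MAPQ ≥ 30 and sex-chromosome
  filters; exact or directional UMI deduplication (adjacency network,
  edge `u→v` iff Hamming 1 and `count(u) ≥ 2·count(v) − 1`); QC
  statistics (off-site fraction, error rate
  `100·(D + I + mismatches) / aligned bases`, UMI base composition,
  Watson-strand fraction).
* **Copy-number profiling**: fixed windows (1 Mb … 30 kb), median
  normalisation to log2 ratios, circular binary segmentation
  (exhaustive max-t arc + permutation test, α = 0.01, 1000
  permutations), ternary calls at `log2(2.5/2)` / `log2(1.5/2)`,
  fluctuation (mean ± SD of |raw − segmented|), aneuploid genome
  fraction, profile correlations, amp/del segment lengths.
* **Heterogeneity**: gene-state matrices (amplified = 1, deleted = −1,
  neutral = 0), recurrence ranking, Euclidean/complete-linkage sample
  clustering with Newick export, replicate concordance
  (Pearson ρ + slope of amp/del genome fractions), two-sided
  Mann-Whitney burden comparison.

## Worked example

Simulate one barcoded sample on a 1-Mb genome with a 200-kb
amplification (copy 4) and a 100-kb hemizygous deletion (copy 1), then
recover the profile:

```r
library(rrcna)
enz <- enzyme("NlaIII")
lengths <- c(chr1 = 1e6)
genome <- sim_genome(lengths, gc = 0.41, seed = 1)
truth <- copy_number_truth(data.frame(
  sample = "tumourA", chrom = "chr1",
  start = c(1, 300001, 500001, 700001, 800001),
  end   = c(300000, 500000, 700000, 800000, 1000000),
  copy  = c(2, 4, 2, 1, 2)), lengths)
sim <- sim_molecules(genome, truth, enz, lambda_per_copy = 3, seed = 2)
rr  <- sim_reads(sim, c(tumourA = "ACGTACGT"), pcr_dup_mean = 1,
                 subst_error_rate = 0.005, seed = 3)
res <- process_reads(rr$reads, genome, enz, c(tumourA = "ACGTACGT"))
prof <- cn_profile(res$molecules, bin_grid(lengths, bin_size = 2.5e4), seed = 4)
prof$segments
```

This prints (97,899 simulated reads):

```
prefix parsed: 100.0% | off-site: 9.38% | error rate: 0.499% | Watson fraction: 0.497
<cn_profile> tumourA: 40 bins (0 missing), 5 segments, 30.0% aneuploid
    chrom start_bin end_bin n_bins          mean
1:   chr1         1      12     12  0.0388400626
2:   chr1        13      20      8  0.9684399389
3:   chr1        21      28      8 -0.1022387661
4:   chr1        29      32      4 -0.9145967893
5:   chr1        33      40      8 -0.0006425315
```

Reading the output: the recovered error rate (0.499%) matches the
injected 0.5% substitution rate; molecules split evenly between Watson
and Crick strands (0.497); the off-site fraction reflects reads whose
20-nt seed carries an error (1 − 0.995²⁰ ≈ 9.5%) and is 0% in an
error-free run. The segmentation recovers the amplification exactly
(bins 13–20, i.e. 300–500 kb, mean log2 ≈ 0.97 ≈ log2(4/2)) and the
deletion (bins 29–32, 700–800 kb, mean ≈ −0.91 ≈ log2(1/2)); with the
half-copy thresholds ±`log2(2.5/2)`/`log2(1.5/2)` this gives a 30%
aneuploid genome fraction (12 of 40 bins), matching the simulated
truth.

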