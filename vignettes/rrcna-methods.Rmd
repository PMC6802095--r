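---
title: "Reduced-representation copy-number analysis with rrcna: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-representation copy-number analysis with rrcna: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrcna)
```

## Overview

`rrcna` implements the computational side of restriction-site-anchored
reduced-representation DNA sequencing of the CUTseq family. In this
library design, genomic DNA is digested with a restriction endonuclease
(the built-ins are the four-base cutter NlaIII, `CATG`, and the six-base
cutter HindIII, `AAGCTT`), and adapters carrying an 8-nt unique molecular
identifier (UMI) and an 8-nt sample barcode are ligated at the cut sites.
After pooling and amplification, each sequenced read therefore begins
with a fixed 16-nt prefix (UMI then barcode) followed by a genomic insert
whose 5' end coincides with an enzyme cut coordinate. Because every cut
site contributes one molecule source per flank, reads split evenly
between the Watson and Crick strands, and UMI counting converts reads
into single-molecule counts that are proportional to local DNA copy
number.

The package covers five stages, each usable on its own:

1. **Digest design** — scan genomes for recognition sites and compute the
   statistics used to choose an enzyme: inter-site distance
   distributions, per-window spacing homogeneity, site density in target
   regions, and distances from arbitrary points to the nearest site.
2. **Simulation** — generate synthetic genomes, ground-truth integer
   copy-number landscapes, and reads with the full library anatomy, so
   that every downstream stage is testable without external data.
3. **Read processing** — prefix parsing, mismatch-tolerant
   demultiplexing, cut-site anchoring, MAPQ and sex-chromosome filters,
   and UMI deduplication (exact and directional).
4. **Copy-number profiling** — fixed-window binning, median
   normalisation, circular binary segmentation (CBS), and ternary
   amplification/deletion calls at fixed log2 thresholds.
5. **Heterogeneity analytics** — gene-state matrices, recurrence
   ranking, complete-linkage clustering, replicate concordance, and a
   Mann-Whitney burden comparison.

## Coordinate conventions

All user-facing tables use 1-based, inclusive coordinates, the native
convention of R and Bioconductor containers. BED input and output is
converted at the boundary (`read_bed()`, `write_bed()`), since BED is
0-based half-open. Inter-site distances are differences of
recognition-start coordinates, never across chromosome boundaries; the
cut offsets only matter for read anchoring.

All descriptive "mean ± SD" summaries use the population SD (divide by
*n*): these are descriptions of observed distributions, not inferential
estimates. Recognition-site windows containing `N` are never sites, but
distances spanning assembly gaps are kept as-is.

## Cut geometry and read anchoring

For a palindromic enzyme the bottom-strand cut offset is the mirror of
the top-strand offset (`length - cut_offset_top`). A Watson-strand read
starts at the 5'-most cut position and runs into the right flank; a
Crick-strand read starts at the 3'-most cut position and runs, reverse
complemented, into the left flank. For NlaIII (`CATG^`, 3' overhang)
this places the Watson anchor at the recognition start and the Crick
anchor at recognition start + 4, so reads on both strands begin with
`CATG` — a convenient sanity check. For HindIII (`A^AGCTT`, 5'
overhang) the anchors are recognition start + 1 and + 5.

`anchor_reads()` substitutes for an external aligner at simulator scale:
the first 20 nt of the insert (equal to the minimum accepted insert) are
located by exact match against both strands via a genome k-mer index.
Absent seeds leave a read off-site, repeated seeds discard it as
multi-mapping, and a uniquely placed read is anchored when its 5'
coordinate lies within 3 bp of the expected strand-specific cut
coordinate of the nearest site (the tolerance absorbs overhang-end
ambiguity and is configurable). Alignment statistics — aligned bases and
mismatches, feeding the error-rate estimator — are accumulated over the
*post-seed* portion of the insert only: the seed matched exactly by
construction, so counting its bases would bias the estimated
substitution rate downward by a factor of roughly
(insert − seed)/insert. Real data processed from SAM/BAM
(`anchor_sam()`) instead trusts the aligner's coordinates, MAPQ and
CIGAR/NM statistics, and applies only the ≥ 30 MAPQ filter (inclusive),
sex-chromosome exclusion, anchoring and deduplication.

Ambiguous barcodes — two whitelist entries at the same minimal Hamming
distance within the two-mismatch tolerance — are rejected rather than
assigned at random, preventing sample bleed-through; `N` counts as a
mismatch. Whitelists are expected to keep pairwise Hamming distance ≥ 5
so that two-mismatch assignment is unambiguous; violations warn but do
not error.

## The generative model of the simulator

The simulator's defaults describe the study conditions under which the
package's recovery properties are stated:

* **Genomes** are i.i.d. base sequences at a requested GC fraction
  (default 0.41, about human). They contain no repeats, no assembly
  gaps, and no centromeres; multi-mapping and mappability artifacts of
  real genomes are therefore *not* exercised, which is the main caveat
  when transferring test results to real data.
* **Molecule counts**: each (site, strand, sample) source draws an
  independent Poisson count with mean `lambda_per_copy × copy`, the
  copy number taken from the truth interval containing the recognition
  start. Poisson is the minimal i.i.d. sampling model; it makes
  depth/recovery analyses tractable and gives the even Watson/Crick
  partitioning expected of clean libraries. Sources whose maximal
  insert is shorter than 20 nt are dropped, emulating size selection.
* **UMIs** are uniform over the 4^8 8-mers, so per-position base
  composition is balanced at 0.25. Collisions are allowed and not
  corrected, as in plain UMI counting; see "Numerical choices" below.
* **PCR duplicates**: each molecule emits `1 + D` reads with
  `D ~ Poisson(pcr_dup_mean)` (a geometric alternative is available).
  Duplicates inherit the molecule's UMI *before* sequencing errors, so
  substitution errors can corrupt duplicate UMIs — exactly the
  situation the directional deduplication rule exists for.
* **Substitution errors** are i.i.d. per base over the entire read,
  prefix included, at the configured rate (default 0.005). Indels,
  quality-dependent errors, GC amplification bias and FFPE artifacts
  are not modelled; qualities are constant `I`.
* **Inserts** run from the strand-specific cut anchor to the
  neighbouring cut site or chromosome end, truncated at
  `read_length − 16` (default read length 76).

Everything is deterministic given a seed; identical seeds give
byte-identical FASTQ.

## UMI deduplication

Reads are grouped strictly by (chromosome, anchored site, strand,
sample). `exact` counts distinct UMIs. `directional` reproduces the
default adjacency-network method of the standard UMI-collapsing tools:
a directed edge `u → v` joins UMIs at Hamming distance 1 when
`count(u) ≥ 2·count(v) − 1`; nodes are visited in decreasing count
order (lexicographic tie-break for determinism) and each unvisited node
seeds a molecule that absorbs all nodes reachable along directed edges.
The exact count is always ≥ the directional count.

A consequence worth stating: two *genuine* molecules in one group whose
UMIs collide (identical, or at Hamming distance 1 with near-equal
counts) legitimately collapse into one. Lossless round-trip recovery —
zero errors, zero duplication, molecule counts equal to truth exactly —
is therefore an event of high probability, not a certainty; at the
scales used in the tests (~100 same-group UMI pairs) the expected
number of collisions is below 0.05. The test suite asserts exactness on
collision-free groups and bounds the frequency of the exception.

## Copy-number profiling

Bins are non-overlapping fixed-size windows tiling the autosomes (sex
chromosomes are excluded by default so genomic support stays comparable
across samples); the last bin of a chromosome may be short. Counts are
scaled by the median over informative bins and log2-transformed, so the
modal (diploid) state sits at 0. Two choices here are deliberate
simplifications relative to FFPE-tuned bin-count normalisers, and are
documented as such: there is no mappability or blacklist masking
(meaningless on synthetic genomes; an optional GC-decile correction is
provided), and zero-count bins default to *missing* rather than a
pseudocount — at low depth a log of zero would fabricate deep
deletions. When true homozygous deletions are expected to be resolvable
(as in the recovery analyses below), the `pseudocount` mode assigns
them a strongly negative ratio instead; this is the mode the package's
end-to-end evaluations use, and the default remains `missing`.

### Circular binary segmentation

`segment_cbs()` implements CBS directly: within the current interval
the arc `(i, j]` of the circularised series maximising the absolute
two-sample t-statistic (pooled variance) between in-arc and out-of-arc
bins is found by exhaustive O(n²) search; significance is assessed by
permuting the interval's values (`n_perm = 1000` by default) with an
add-one-corrected p-value, and the interval splits at the arc
boundaries when `p < alpha` (default 0.01), recursing on the pieces.
Segment values are the arithmetic means of their bins — the
least-squares values given the breakpoints — so splitting never
increases the residual sum of squares. Chromosomes segment
independently (per-arm segmentation would need centromere annotation,
which synthetic genomes lack; supplying arm-level "chromosomes" achieves
it). No hybrid speed-up and no segment-merging prune are applied by
default. The permutation seed is mandatory: identical seeds give
identical segmentations.

Two properties of the permutation test are worth knowing. First, an arc
and its complement describe the same split with the same |t|, so
comparisons against exhaustive search must canonicalise to the induced
breakpoints. Second, the test has a granularity floor: on a 10-bin
chromosome a 5/5 bimodal split can never reach p < 0.01, because ~4% of
circular shuffles place the five high bins contiguously. Detection at
`alpha = 0.01` therefore needs interval sizes where contiguous null
arrangements are rare; the package's recovery analyses use ≥ 20 bins
per chromosome.

### Calling and profile statistics

Ternary calls use the fixed half-copy thresholds `log2(2.5/2) ≈ +0.322`
(amplified) and `log2(1.5/2) ≈ −0.415` (deleted) on segmented values;
missing bins are called 0 and flagged. Profile-level statistics follow
directly: signal fluctuation is the mean ± SD of |raw − segmented| over
informative bins; the aneuploid fraction is the percentage of
informative bins called non-neutral; profile similarity is the Pearson
correlation of per-bin values (segmented by default, raw optionally —
the choice is exposed because published figures do not always state
which was used); amplified/deleted segment lengths are maximal
same-call runs merged within chromosomes.

## Heterogeneity analytics

Gene states project bin-level calls onto genes: a gene takes the state
of the call class overlapping the largest fraction of it. How a gene
spanning several differently-called segments should be labelled is
genuinely open, so the package fixes the ties explicitly: a non-neutral
state beats neutral on an exact tie, and an exact +1/−1 tie yields 0
with a conflict flag. Recurrence ranking orders genes by the number of
samples in a state, ties broken lexicographically. Sample clustering is
Euclidean distance plus complete linkage via `stats::hclust` — the same
routine the original analyses used — with an exhaustive agglomerative
re-implementation serving as the oracle in the test suite; dendrograms
export to Newick via `ape`. Replicate concordance correlates the
amplified and deleted genome fractions across replicate pairs (pooled,
as in the published figures, and per state) with a least-squares slope.
The burden comparison is the two-sided Mann-Whitney test via
`stats::wilcox.test`, which uses the exact null distribution for small
untied samples and the tie-corrected normal approximation otherwise;
the "detectable CNA" entry filter (aneuploid fraction > 0) is the
caller's responsibility since the analysed cohort defines it.

## Problem sizes used in the checks

The packaged evaluations run, on one CPU, with: a 5-Mb single-chromosome
genome, 4 barcoded samples, truth copies {0, 1, 2, 4} in contiguous
blocks aligned to 50-kb bins, λ = 3 molecules/site/copy, one PCR
duplicate per molecule on average and 0.5% substitution errors
(≈ 1.7 M reads) for end-to-end recovery; 100-kb/600-kb genomes for
round-trip and error-rate recovery; 1000 randomised UMI groups for the
deduplication oracle; 200–500 short series for the segmentation
oracle and null calibration; and 100 molecule-level re-simulations of
three two-replicate layouts for clustering behaviour. These sizes were
chosen so each property is measured with comfortable statistical margin
while the whole suite stays desk-scale. The genome-wide digest
statistics for the human reference (NlaIII 210 ± 286 bp, HindIII
3422 ± 3684 bp inter-site distances) require the ~3 GB GRCh37 FASTA on
local disk and are exercised by the same `intersite_distances()` code
path whenever such a file is supplied
(`options(rrcna.grch37_fasta = ...)`); they are not reproducible from
package-internal data.

## Known limitations

* The exact-match locator is for simulator-scale genomes; real reads
  should be aligned externally and ingested from SAM/BAM.
* Synthetic genomes contain no repeats, so the multi-mapping path is
  exercised only by constructed fixtures; mappability-driven biases of
  real genomes are out of scope, as are absolute ploidy estimation,
  tumour purity, and allele-specific copy number.
* UMI grouping is strictly per anchored site and strand; no positional
  fuzziness and no base-quality-aware UMI correction.
* Indel sequencing errors are not simulated (the error-rate estimator
  still accounts for indels when fed CIGAR-derived summaries).
* Degenerate (IUPAC) recognition sequences are rejected; only
  exact-sequence enzymes are supported.
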