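#' Process raw reads into per-sample molecule tables
#'
#' Runs the full read-processing stack on single-end reads: prefix
#' parsing (8 nt UMI + 8 nt sample barcode), mismatch-tolerant barcode
#' assignment, exact-match insert location and cut-site anchoring,
#' MAPQ/sex-chromosome filtering and UMI deduplication; collects the
#' standard QC statistics along the way.
#'
#' @param reads A FASTQ path, a character vector of read sequences, or
#'   the `data.table` from [read_fastq()].
#' @param genome The reference genome (`DNAStringSet`, FASTA path or
#'   character vector).
#' @param enz A [restriction_enzyme()].
#' @param whitelist A [barcode_whitelist()] (named sample -> barcode map).
#' @param max_mismatch Barcode mismatch tolerance (default 2).
#' @param min_insert Minimum insert length in nt (default 20; also the
#'   exact-match seed length).
#' @param tolerance Cut-site anchoring tolerance in bp (default 3).
#' @param mapq_min Mapping-quality cutoff, inclusive (default 30).
#' @param drop_sex_chroms Exclude sex chromosomes (default TRUE).
#' @param dedup_method `"directional"` (default) or `"exact"`.
#' @param kmer_index Optional pre-built [genome_kmer_index()] (rebuilt
#'   from `genome` otherwise).
#' @param sites Optional pre-built [site_index()].
#' @return A list with `molecules` (the deduplicated `molecule_table`),
#'   `qc` (named list: read tallies, off-site percentage, error-rate
#'   percentage, UMI base composition, Watson-strand fraction) and
#'   `anchored` (the per-read anchoring table joined with sample and
#'   UMI).
#' @export
process_reads <- function(reads, genome, enz, whitelist, max_mismatch = 2L,
                          min_insert = 20L, tolerance = 3L, mapq_min = 30L,
                          drop_sex_chroms = TRUE,
                          dedup_method = c("directional", "exact"),
                          kmer_index = NULL, sites = NULL) {
  dedup_method <- match.arg(dedup_method)
  whitelist <- barcode_whitelist(whitelist)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  genome <- as_genome(genome)
  if (is.null(sites)) sites <- site_index(genome, enz)
  if (is.null(kmer_index)) kmer_index <- genome_kmer_index(genome, k = min_insert)

  parsed <- parse_prefix(reads, min_insert = min_insert)
  n_total <- nrow(parsed)
  ok <- is.na(parsed$reject)
  asn <- assign_barcode(parsed$barcode[ok], whitelist, max_mismatch = max_mismatch)
  parsed[ok, `:=`(sample = asn$sample, bc_status = asn$status)]
  parsed[!ok, bc_status := "rejected"]

  usable <- parsed[ok][asn$status == "assigned"]
  anchored <- anchor_reads(usable, kmer_index, sites, tolerance = tolerance)
  anchored <- merge(anchored, usable[, .(read_id, sample, umi)],
                    by = "read_id", sort = FALSE)

  flt <- filter_reads(anchored[anchored$status == "anchored"],
                      mapq_min = mapq_min, drop_sex_chroms = drop_sex_chroms)
  molecules <- dedup_umis(flt$reads, method = dedup_method)

  qc <- list(
    reads_total = n_total,
    prefix_parsed_pct = 100 * sum(ok) / max(1L, n_total),
    barcode_tally = c(table(parsed$bc_status)),
    offsite_pct = site_overlap_fraction(anchored),
    error_rate_pct = error_rate(anchored[anchored$status == "anchored"]),
    umi_composition = if (nrow(usable)) umi_base_composition(usable$umi) else NULL,
    filter_tally = flt$tally,
    watson_fraction = if (nrow(molecules)) strand_partition(molecules) else NA_real_,
    reads_per_molecule = if (nrow(molecules)) nrow(flt$reads) / sum(molecules$molecules)
                         else NA_real_)
  list(molecules = molecules, qc = qc, anchored = anchored)
}
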