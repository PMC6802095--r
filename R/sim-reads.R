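BASES <- c("A", "C", "G", "T")
PREFIX_LEN <- 16L   # 8 nt UMI + 8 nt sample barcode
UMI_LEN <- 8L

# Vectorised integer (0 .. 4^8-1) -> 8-mer UMI string.
int2umi <- function(x) {
  cols <- lapply(7:0, function(k) BASES[(x %/% 4L^k) %% 4L + 1L])
  do.call(paste0, cols)
}

#' Generate random sample barcodes
#'
#' Draws 8-nt barcodes with a guaranteed pairwise Hamming distance, so
#' that demultiplexing with up to two mismatches is unambiguous.
#'
#' @param n Number of barcodes.
#' @param seed Integer random seed.
#' @param min_dist Minimum pairwise Hamming distance (default 5).
#' @return Named character vector (`S1`, `S2`, ...).
#' @export
make_barcodes <- function(n, seed = 1L, min_dist = 5L) {
  set.seed(seed)
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < 10000L) {
    cand <- paste(sample(BASES, 8L, replace = TRUE), collapse = "")
    if (all(vapply(out, function(b) hamming(b, cand), integer(1)) >= min_dist)) {
      out <- c(out, cand)
    }
    tries <- tries + 1L
  }
  if (length(out) < n) stop("could not generate enough distant barcodes", call. = FALSE)
  setNames(out, paste0("S", seq_len(n)))
}

# Per-site read-source geometry on one chromosome: anchor coordinates and
# the maximum insert each (site, strand) source can yield. A Watson read
# runs 5'->3' from the cut into the right flank, a Crick read from the cut
# into the left flank (reverse-complemented); inserts are bounded by the
# neighbouring cut site or the chromosome end.
site_geometry <- function(sites, chrom_len, enz) {
  m <- length(sites)
  wA <- watson_anchor(sites, enz)
  cA <- crick_anchor(sites, enz)
  frag_hi <- c(if (m > 1L) cA[-1L], chrom_len)       # right boundary for Watson source i
  frag_lo <- c(1L, if (m > 1L) wA[-m])               # left boundary for Crick source i
  data.table::data.table(
    site = sites, watson_anchor = wA, crick_anchor = cA,
    watson_avail = pmax(0L, frag_hi - wA + 1L),
    crick_avail = pmax(0L, cA - frag_lo + 1L))
}

#' Simulate ground-truth molecule counts at cut sites
#'
#' Every cut site contributes two independent molecule sources, one per
#' flank (Watson and Crick strands). The molecule count of each
#' (site, strand, sample) source is Poisson with mean
#' `lambda_per_copy * c`, where `c` is the integer copy number of the
#' truth interval containing the recognition start. Sources whose maximal
#' insert is shorter than `min_insert` are dropped, emulating size
#' selection.
#'
#' @param genome A `DNAStringSet` (or FASTA path / character vector).
#' @param truth A [copy_number_truth()].
#' @param enz A [restriction_enzyme()].
#' @param lambda_per_copy Mean molecules per site, per strand and per copy.
#' @param min_insert Minimum insert length in nt (default 20).
#' @param seed Integer random seed.
#' @return An object of class `simulation_truth`: the genome, enzyme,
#'   truth intervals, a `molecules` table (`sample`, `chrom`, `site`,
#'   `strand`, `count`) and the per-site geometry.
#' @export
sim_molecules <- function(genome, truth, enz, lambda_per_copy = 3,
                          min_insert = 20L, seed = 1L) {
  check_scalar_number(lambda_per_copy, "lambda_per_copy", lower = 1e-9)
  genome <- as_genome(genome)
  idx <- site_index(genome, enz)
  if (sum(lengths(idx$sites)) == 0L) {
    stop("the enzyme has no recognition sites in this genome; ",
         "use a longer genome or a more frequent (4-base) cutter", call. = FALSE)
  }
  set.seed(seed)
  samples <- unique(truth$sample)
  rows <- list()
  geom_all <- list()
  for (chr in names(idx$sites)) {
    p <- idx$sites[[chr]]
    if (length(p) == 0L) next
    geom <- site_geometry(p, idx$chrom_lengths[[chr]], enz)
    geom_all[[chr]] <- data.table::copy(geom)[, chrom := chr]
    for (s in samples) {
      cn <- copy_at(truth, s, chr, p)
      for (strand in c("+", "-")) {
        avail <- if (strand == "+") geom$watson_avail else geom$crick_avail
        ok <- avail >= min_insert
        cnt <- integer(length(p))
        cnt[ok] <- rpois(sum(ok), lambda_per_copy * cn[ok])
        keep <- cnt > 0L
        if (any(keep)) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            sample = s, chrom = chr, site = p[keep], strand = strand,
            count = cnt[keep])
        }
      }
    }
  }
  mol <- data.table::rbindlist(rows)
  data.table::setorder(mol, sample, chrom, site, strand)
  structure(
    list(genome = genome, enzyme = enz, truth = truth, molecules = mol,
         geometry = data.table::rbindlist(geom_all),
         params = list(lambda_per_copy = lambda_per_copy,
                       min_insert = as.integer(min_insert), seed = seed)),
    class = "simulation_truth"
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d samples, %d molecule sources, %s sites, enzyme %s\n",
              length(unique(x$molecules$sample)), nrow(x$molecules),
              format(nrow(x$geometry), big.mark = ","), x$enzyme$name))
  invisible(x)
}

# In-place i.i.d. substitution errors over a character vector of reads.
# Exact per-base Bernoulli model, applied to the whole read including the
# UMI/barcode prefix. Operates on the concatenated byte stream for speed.
apply_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  nch <- nchar(reads)
  big <- charToRaw(paste(reads, collapse = ""))
  n <- length(big)
  chunk <- 2e7L
  err <- integer(0)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    hits <- which(runif(hi - lo + 1L) < rate)
    if (length(hits)) err <- c(err, lo - 1L + hits)
  }
  if (length(err)) {
    base_raw <- charToRaw("ACGT")
    cur <- match(big[err], base_raw)               # 1..4
    shift <- sample.int(3L, length(err), replace = TRUE)
    big[err] <- base_raw[(cur - 1L + shift) %% 4L + 1L]
  }
  ends <- cumsum(nch)
  starts <- ends - nch + 1L
  substring(rawToChar(big), starts, ends)
}

#' Simulate reads from ground-truth molecules
#'
#' Each truth molecule receives a fresh UMI drawn uniformly from the 4^8
#' 8-mers (collisions allowed, as in plain UMI counting) and emits
#' `1 + D` reads, where `D` is the number of PCR duplicates (Poisson or
#' geometric with mean `pcr_dup_mean`). Read anatomy is
#' `UMI (8 nt) + sample barcode (8 nt) + genomic insert`: Watson reads run
#' 5'->3' from the cut into the right flank, Crick reads from the cut into
#' the left flank (reverse-complemented); inserts are truncated at
#' `read_length - 16` nt or the next cut site. Substitution errors are
#' applied i.i.d. per base over the whole read, prefix included, so
#' duplicate reads can carry corrupted copies of their molecule's UMI.
#' Base qualities are constant `"I"`.
#'
#' @param sim A [sim_molecules()] result.
#' @param barcodes Named character vector, sample name -> 8-nt barcode;
#'   every sample in the truth must be present. Pairwise Hamming distance
#'   below 5 triggers a warning (two-mismatch demultiplexing may become
#'   ambiguous).
#' @param read_length Total read length in nt (default 76).
#' @param pcr_dup_mean Mean number of PCR duplicates per molecule.
#' @param subst_error_rate Per-base substitution probability.
#' @param dup_model `"poisson"` (default) or `"geometric"`.
#' @param seed Integer random seed.
#' @param fastq Optional path; when given, reads are written as FASTQ.
#' @return A list with `reads` (`data.table`: `read_id`, `seq`),
#'   `provenance` (`read_id`, `molecule_id`, `sample`, `chrom`, `site`,
#'   `strand`, `umi`) and `fastq` (path or `NULL`).
#' @export
sim_reads <- function(sim, barcodes, read_length = 76L, pcr_dup_mean = 1,
                      subst_error_rate = 0.005,
                      dup_model = c("poisson", "geometric"),
                      seed = 1L, fastq = NULL) {
  stopifnot(inherits(sim, "simulation_truth"))
  dup_model <- match.arg(dup_model)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in map", call. = FALSE)
  if (any(nchar(barcodes) != 8L)) stop("barcodes must be 8 nt long", call. = FALSE)
  if (length(barcodes) > 1L) {
    pd <- combn(barcodes, 2L, function(p) hamming(p[1], p[2]))
    if (min(pd) < 5L) warning("barcode pairs closer than Hamming distance 5; ",
                              "two-mismatch demultiplexing may be ambiguous")
  }
  missing_bc <- setdiff(unique(sim$molecules$sample), names(barcodes))
  if (length(missing_bc)) stop("no barcode for sample(s): ",
                               paste(missing_bc, collapse = ", "), call. = FALSE)
  max_insert <- as.integer(read_length) - PREFIX_LEN
  if (max_insert < sim$params$min_insert) {
    stop("read_length too short for the minimum insert", call. = FALSE)
  }
  set.seed(seed)

  mol <- sim$molecules[rep(seq_len(nrow(sim$molecules)), sim$molecules$count)]
  mol[, count := NULL]
  mol[, molecule_id := seq_len(.N)]
  mol[, umi := int2umi(sample.int(4L^UMI_LEN, .N, replace = TRUE) - 1L)]

  n_dup <- switch(dup_model,
                  poisson = rpois(nrow(mol), pcr_dup_mean),
                  geometric = stats::rgeom(nrow(mol), 1 / (1 + pcr_dup_mean)))
  reads <- mol[rep(seq_len(nrow(mol)), 1L + n_dup)]
  reads[, read_id := sprintf("read%07d", seq_len(.N))]

  # genomic insert per read
  geom <- sim$geometry
  gkey <- paste(geom$chrom, geom$site)
  gi <- match(paste(reads$chrom, reads$site), gkey)
  chrom_seq <- setNames(as.character(sim$genome), names(sim$genome))
  plus <- reads$strand == "+"
  ins_start <- ins_end <- integer(nrow(reads))
  wA <- geom$watson_anchor[gi]; cA <- geom$crick_anchor[gi]
  avail_w <- geom$watson_avail[gi]; avail_c <- geom$crick_avail[gi]
  ins_start[plus] <- wA[plus]
  ins_end[plus] <- wA[plus] + pmin(max_insert, avail_w[plus]) - 1L
  ins_end[!plus] <- cA[!plus]
  ins_start[!plus] <- cA[!plus] - pmin(max_insert, avail_c[!plus]) + 1L
  insert <- substring(chrom_seq[reads$chrom], ins_start, ins_end)
  insert[!plus] <- revcomp(insert[!plus])
  seqs <- paste0(reads$umi, barcodes[reads$sample], insert)
  seqs <- apply_substitutions(seqs, subst_error_rate)

  out_reads <- data.table::data.table(read_id = reads$read_id, seq = seqs)
  prov <- reads[, .(read_id, molecule_id, sample, chrom, site, strand, umi)]
  if (!is.null(fastq)) {
    qual <- strrep("I", nchar(seqs))
    lines <- rbind(paste0("@", out_reads$read_id), seqs, "+", qual)
    writeLines(as.vector(lines), fastq)
  }
  list(reads = out_reads, provenance = prov, fastq = fastq)
}

#' Read single-end FASTQ sequences
#'
#' @param path FASTQ file path.
#' @return `data.table` with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table::data.table(read_id = sub("\\s.*$", "", names(x)),
                         seq = as.character(x))
}
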