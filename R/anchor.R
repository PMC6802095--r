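# 2-bit base codes as a raw vector: A=0, C=1, G=2, T=3, anything else 0xFF.
base2_codes <- function(x) {
  r <- charToRaw(x)
  out <- rep(as.raw(0xFF), length(r))
  out[r == charToRaw("A")] <- as.raw(0L)
  out[r == charToRaw("C")] <- as.raw(1L)
  out[r == charToRaw("G")] <- as.raw(2L)
  out[r == charToRaw("T")] <- as.raw(3L)
  out
}

# Rolling numeric codes of all k-mers of a sequence (exact for k <= 26 in
# a double); windows containing non-ACGT bases get NA.
kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  z <- numeric(m)
  bad <- logical(m)
  for (j in 0:(k - 1L)) {
    b <- codes[(1L + j):(m + j)]
    bad <- bad | b == as.raw(0xFF)
    z <- z * 4 + as.integer(b)
  }
  z[bad] <- NA_real_
  z
}

#' Build an exact-match k-mer index of a genome
#'
#' Records a 2-bit-packed numeric code of the forward-strand k-mer
#' starting at every position of every chromosome (k-mers containing `N`
#' are skipped). Used by [anchor_reads()] to locate inserts by exact
#' match of their first `k` bases; suitable for simulator-scale genomes
#' (tens of megabases). Reverse-strand hits are found by looking up the
#' reverse-complement code of the query, so the index itself stores one
#' strand only.
#'
#' @param genome A `DNAStringSet` (or FASTA path / character vector).
#' @param k Seed length in nt (default 20, the minimum insert length;
#'   at most 26 so codes stay exact in a double).
#' @return A keyed `data.table` (`code`, `chrom`, `pos`) of class
#'   `genome_kmer_index` with attributes `k`, `chrom_lengths` and
#'   `chrom_seq`.
#' @export
genome_kmer_index <- function(genome, k = 20L) {
  genome <- as_genome(genome)
  k <- as.integer(k)
  stopifnot(k >= 8L, k <= 26L)
  chrom_seq <- setNames(as.character(genome), names(genome))
  parts <- lapply(names(genome), function(chr) {
    z <- kmer_codes(base2_codes(chrom_seq[[chr]]), k)
    if (length(z) == 0L) return(NULL)
    keep <- !is.na(z)
    data.table::data.table(code = z[keep], chrom = chr,
                           pos = seq_along(z)[keep])
  })
  idx <- data.table::rbindlist(parts)
  data.table::setkey(idx, code)
  data.table::setattr(idx, "k", k)
  data.table::setattr(idx, "chrom_lengths",
                      setNames(Biostrings::width(genome), names(genome)))
  data.table::setattr(idx, "chrom_seq", chrom_seq)
  data.table::setattr(idx, "class", c("genome_kmer_index", class(idx)))
  idx[]
}

# Forward and reverse-complement codes of fixed-width seeds (character
# vector, all of width k). Returns list(fwd, rev); NA where the seed
# contains non-ACGT bases.
seed_codes <- function(seeds, k) {
  n <- length(seeds)
  if (n == 0L) return(list(fwd = numeric(0), rev = numeric(0)))
  codes <- base2_codes(paste(seeds, collapse = ""))
  fwd <- numeric(n); rev <- numeric(n); bad <- logical(n)
  sel <- seq(0L, by = k, length.out = n)
  for (j in 1:k) {
    b <- codes[sel + j]
    bad <- bad | b == as.raw(0xFF)
    bi <- as.integer(b)
    fwd <- fwd + bi * 4^(k - j)
    rev <- rev + (3 - bi) * 4^(j - 1L)
  }
  fwd[bad] <- NA_real_
  rev[bad] <- NA_real_
  list(fwd = fwd, rev = rev)
}

# Expected 5' coordinates of site-anchored reads for one chromosome.
expected_anchors <- function(sites, enz, strand) {
  if (strand == "+") watson_anchor(sites, enz) else crick_anchor(sites, enz)
}

# Minimum |pos - anchor| and the recognition start of the nearest anchor,
# for sorted anchor coordinates. Returns list(distance, site).
nearest_anchor <- function(pos, anchors, site_starts) {
  if (length(anchors) == 0L) {
    return(list(distance = rep(NA_real_, length(pos)),
                site = rep(NA_integer_, length(pos))))
  }
  k <- findInterval(pos, anchors)
  lo <- pmax(k, 1L)
  hi <- pmin(k + 1L, length(anchors))
  d_lo <- abs(pos - anchors[lo])
  d_hi <- abs(anchors[hi] - pos)
  pick <- ifelse(d_lo <= d_hi, lo, hi)
  list(distance = pmin(d_lo, d_hi), site = site_starts[pick])
}

#' Locate inserts in the genome and anchor them to cut sites
#'
#' Substitute for external short-read alignment at simulator scale: the
#' first `k` bases of each insert (the seed) are located by exact match
#' against both strands of the genome. Reads whose seed occurs more than
#' once are discarded as multi-mapping; reads whose seed is absent are
#' off-site. For uniquely located reads the 5' genomic coordinate is
#' compared with the expected strand-specific cut coordinate of the
#' nearest recognition site; within `tolerance` bp the read is anchored to
#' that site, otherwise it is off-site.
#'
#' Alignment statistics (`aligned_bases`, `mismatches`) are reported over
#' the post-seed portion of the insert, compared base-by-base against the
#' reference: the seed matched exactly by construction, so including it
#' would bias error-rate estimates. Uniquely located reads get a mapping
#' quality of 60, multi-mapping reads 0.
#'
#' @param parsed Output of [parse_prefix()] (rejected rows are ignored).
#' @param index A [genome_kmer_index()] of the same genome.
#' @param sites A [site_index()] for the enzyme in use.
#' @param tolerance Maximum distance in bp between the read 5' coordinate
#'   and the expected cut coordinate (default 3).
#' @return `data.table` with `read_id`, `status`
#'   (`anchored`/`offsite`/`multimap`), `chrom`, `pos5`, `strand`, `mapq`,
#'   `site`, `site_distance`, `aligned_bases`, `mismatches`,
#'   `insertions`, `deletions`.
#' @export
anchor_reads <- function(parsed, index, sites, tolerance = 3L) {
  stopifnot(inherits(index, "genome_kmer_index"), inherits(sites, "site_index"))
  k <- attr(index, "k")
  chrom_lengths <- attr(index, "chrom_lengths")
  chrom_seq <- attr(index, "chrom_seq")
  p <- parsed[is.na(parsed$reject) & nchar(parsed$insert) >= k]
  n <- nrow(p)
  out <- data.table::data.table(
    read_id = p$read_id, status = "offsite", chrom = NA_character_,
    pos5 = NA_integer_, strand = NA_character_, mapq = 0L,
    site = NA_integer_, site_distance = NA_real_,
    aligned_bases = 0L, mismatches = 0L, insertions = 0L, deletions = 0L)
  if (n == 0L) return(out)

  sc <- seed_codes(substr(p$insert, 1L, k), k)
  q <- data.table::data.table(qid = rep(seq_len(n), 2L),
                              code = c(sc$fwd, sc$rev),
                              qstrand = rep(c("+", "-"), each = n))
  q <- q[!is.na(q$code)]
  hits <- index[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(out)

  nh <- hits[, .N, by = qid]
  multi <- nh$qid[nh$N > 1L]
  out$status[multi] <- "multimap"
  h1 <- hits[hits$qid %in% nh$qid[nh$N == 1L]]
  if (nrow(h1) == 0L) return(out)

  ri <- h1$qid
  pos5 <- ifelse(h1$qstrand == "+", h1$pos, h1$pos + k - 1L)
  len <- nchar(p$insert)[ri]
  g_lo <- ifelse(h1$qstrand == "+", pos5, pos5 - len + 1L)
  g_hi <- ifelse(h1$qstrand == "+", pos5 + len - 1L, pos5)
  inb <- g_lo >= 1L & g_hi <= chrom_lengths[h1$chrom]
  out$chrom[ri] <- h1$chrom
  out$strand[ri] <- h1$qstrand
  out$pos5[ri] <- as.integer(pos5)
  out$mapq[ri] <- 60L

  # nearest expected cut coordinate, per chromosome and strand
  for (chr in unique(h1$chrom)) {
    site_starts <- sites$sites[[chr]]
    for (st in c("+", "-")) {
      sel <- which(h1$chrom == chr & h1$qstrand == st & inb)
      if (length(sel) == 0L) next
      na <- nearest_anchor(pos5[sel],
                           expected_anchors(site_starts, sites$enzyme, st),
                           site_starts)
      rr <- ri[sel]
      out$site_distance[rr] <- na$distance
      hit <- !is.na(na$distance) & na$distance <= tolerance
      out$status[rr[hit]] <- "anchored"
      out$site[rr[hit]] <- na$site[hit]
    }
  }

  # post-seed verification against the reference
  ver <- which(inb & len > k)
  if (length(ver) > 0L) {
    pl <- h1$qstrand[ver] == "+"
    g_rem <- character(length(ver))
    g_rem[pl] <- substring(chrom_seq[h1$chrom[ver][pl]],
                           g_lo[ver][pl] + k, g_hi[ver][pl])
    if (any(!pl)) {
      g_rem[!pl] <- revcomp(substring(chrom_seq[h1$chrom[ver][!pl]],
                                      g_lo[ver][!pl], g_hi[ver][!pl] - k))
    }
    read_rem <- substring(p$insert[ri[ver]], k + 1L)
    out$aligned_bases[ri[ver]] <- len[ver] - k
    out$mismatches[ri[ver]] <- count_mismatches(read_rem, g_rem)
  }
  out[]
}

# Vectorised per-pair mismatch counts for equal-length string pairs.
count_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  la <- nchar(a); lb <- nchar(b)
  bad <- la != lb | lb == 0L
  out <- integer(length(a))
  out[bad] <- la[bad]                     # unverifiable portion counts as mismatched
  idx <- which(!bad & la > 0L)
  if (length(idx) > 0L) {
    ra <- charToRaw(paste(a[idx], collapse = ""))
    rb <- charToRaw(paste(b[idx], collapse = ""))
    neq <- as.integer(ra != rb)
    grp <- rep.int(seq_along(idx), la[idx])
    out[idx] <- as.integer(rowsum(neq, grp)[, 1L])
  }
  out
}

#' Filter anchored reads by mapping quality and chromosome
#'
#' Retains reads with mapping quality at or above `mapq_min` (the >= 30
#' cutoff is inclusive) and, by default, drops reads on sex chromosomes so
#' that genomic support regions stay comparable across samples.
#'
#' @param anchored Output of [anchor_reads()] (or a SAM-derived table with
#'   the same columns).
#' @param mapq_min Minimum mapping quality (default 30).
#' @param drop_sex_chroms Drop reads on sex chromosomes (default TRUE).
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return List with `reads` (retained rows) and `tally` (named counts of
#'   removal reasons; low-MAPQ is assessed first).
#' @export
filter_reads <- function(anchored, mapq_min = 30L, drop_sex_chroms = TRUE,
                         sex_chroms = c("chrX", "chrY", "X", "Y")) {
  low <- anchored$mapq < mapq_min
  sexy <- !low & drop_sex_chroms & !is.na(anchored$chrom) &
    anchored$chrom %in% sex_chroms
  keep <- !low & !sexy
  list(reads = anchored[keep],
       tally = c(kept = sum(keep), low_mapq = sum(low), sex_chrom = sum(sexy)))
}

#' Fraction of aligned reads not overlapping a restriction site
#'
#' @param anchored Output of [anchor_reads()].
#' @return Percentage of off-site reads among all located/aligned reads
#'   (`NA` with a warning when the input is empty).
#' @export
site_overlap_fraction <- function(anchored) {
  n <- nrow(anchored)
  if (n == 0L) {
    warning("no aligned reads; off-site fraction undefined")
    return(NA_real_)
  }
  100 * sum(anchored$status == "offsite") / n
}

#' Import anchored reads from a SAM/BAM file
#'
#' Ingestion path for externally aligned real data: the aligner's
#' coordinates and MAPQ are trusted, and only cut-site anchoring and the
#' standard filters are applied downstream. Read names of the form
#' `name:UMI:SAMPLE` supply per-read UMI and sample. CIGAR strings are
#' summarised into aligned bases, insertions and deletions; mismatches are
#' taken from the `NM` tag minus indel bases when present.
#'
#' @param path SAM or BAM file.
#' @param sites A [site_index()].
#' @param tolerance Anchoring tolerance in bp (default 3).
#' @return `data.table` shaped like the output of [anchor_reads()], plus
#'   `sample` and `umi` columns when parseable from read names.
#' @export
anchor_sam <- function(path, sites, tolerance = 3L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM files", call. = FALSE)
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "mapq", "cigar"),
    tag = "NM")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  }
  b <- Rsamtools::scanBam(path, param = prm)[[1]]
  ok <- !is.na(b$pos)
  cig <- b$cigar[ok]
  ref_w <- cigar_sum(cig, c("M", "D", "N", "=", "X"))
  aligned <- cigar_sum(cig, c("M", "=", "X"))
  ins <- cigar_sum(cig, "I")
  del <- cigar_sum(cig, "D")
  nm <- b$tag$NM[ok]
  mm <- pmax(0L, ifelse(is.na(nm), 0L, nm) - ins - del)
  strand <- as.character(b$strand[ok])
  pos5 <- ifelse(strand == "+", b$pos[ok], b$pos[ok] + ref_w - 1L)
  out <- data.table::data.table(
    read_id = b$qname[ok], status = "offsite",
    chrom = as.character(b$rname[ok]), pos5 = as.integer(pos5),
    strand = strand, mapq = as.integer(b$mapq[ok]),
    site = NA_integer_, site_distance = NA_real_,
    aligned_bases = aligned, mismatches = mm, insertions = ins, deletions = del)
  meta <- data.table::tstrsplit(out$read_id, ":", fixed = TRUE)
  if (length(meta) >= 3L) {
    out[, umi := meta[[2]]]
    out[, sample := meta[[3]]]
  }
  for (chr in intersect(unique(out$chrom), names(sites$sites))) {
    site_starts <- sites$sites[[chr]]
    for (st in c("+", "-")) {
      sel <- which(out$chrom == chr & out$strand == st)
      if (length(sel) == 0L) next
      na <- nearest_anchor(out$pos5[sel],
                           expected_anchors(site_starts, sites$enzyme, st),
                           site_starts)
      out$site_distance[sel] <- na$distance
      hit <- !is.na(na$distance) & na$distance <= tolerance
      out$status[sel][hit] <- "anchored"
      out$site[sel][hit] <- na$site[hit]
    }
  }
  out[]
}

cigar_sum <- function(cigar, ops) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(x) {
    if (length(x) == 0L) return(0L)
    op <- substr(x, nchar(x), nchar(x))
    sum(as.integer(sub(".$", "", x))[op %in% ops])
  }, integer(1))
}
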