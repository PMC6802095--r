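#' Fixed-size genomic bin grid
#'
#' Tiles each (autosomal) chromosome with non-overlapping windows of
#' constant size; the last window of a chromosome may be short. Typical
#' resolutions are 1 Mb, 500 kb, 100 kb, 50 kb and 30 kb.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param bin_size Window size in bp.
#' @param drop_sex_chroms Exclude sex chromosomes (default TRUE).
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return A `bin_grid`: `data.table` with `bin` (1..n), `chrom`, `start`,
#'   `end` (1-based inclusive); attribute `bin_size`.
#' @export
bin_grid <- function(chrom_lengths, bin_size = 1e5, drop_sex_chroms = TRUE,
                     sex_chroms = c("chrX", "chrY", "X", "Y")) {
  check_scalar_number(bin_size, "bin_size", lower = 1)
  if (drop_sex_chroms) {
    chrom_lengths <- chrom_lengths[!names(chrom_lengths) %in% sex_chroms]
  }
  if (length(chrom_lengths) == 0L) stop("no chromosomes left for the grid", call. = FALSE)
  parts <- lapply(names(chrom_lengths), function(chr) {
    starts <- seq(1L, chrom_lengths[[chr]], by = as.integer(bin_size))
    data.table::data.table(chrom = chr, start = starts,
                           end = pmin(starts + as.integer(bin_size) - 1L,
                                      chrom_lengths[[chr]]))
  })
  g <- data.table::rbindlist(parts)
  g[, bin := seq_len(.N)]
  data.table::setcolorder(g, c("bin", "chrom", "start", "end"))
  data.table::setattr(g, "bin_size", as.integer(bin_size))
  data.table::setattr(g, "class", c("bin_grid", class(g)))
  g[]
}

#' Count molecules per genomic bin
#'
#' Each molecule is assigned to the unique bin containing its site
#' position; molecules outside the grid (e.g. on excluded chromosomes)
#' are tallied as unbinned with a warning.
#'
#' @param molecules A `molecule_table` (or any table with `chrom`, `site`
#'   and `molecules` columns) for a single sample; use
#'   `molecules[sample == s]` to subset first.
#' @param grid A [bin_grid()].
#' @return Integer vector of counts, one per grid bin, with attribute
#'   `unbinned`.
#' @export
bin_counts <- function(molecules, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- integer(nrow(grid))
  unbinned <- 0L
  chrom_col <- molecules[["chrom"]]
  for (chr in unique(chrom_col)) {
    rows <- which(chrom_col == chr)
    m <- molecules[rows]
    gsel <- which(grid$chrom == chr)
    if (length(gsel) == 0L) {
      unbinned <- unbinned + sum(m$molecules)
      next
    }
    b <- findInterval(m$site, grid$start[gsel])
    inside <- b >= 1L & m$site <= grid$end[gsel[length(gsel)]]
    unbinned <- unbinned + sum(m$molecules[!inside])
    if (any(inside)) {
      tab <- rowsum(m$molecules[inside], b[inside])
      counts[gsel[as.integer(rownames(tab))]] <- as.integer(tab[, 1L])
    }
  }
  if (unbinned > 0L) {
    warning(unbinned, " molecule(s) fell outside the bin grid")
  }
  attr(counts, "unbinned") <- unbinned
  counts
}

#' Normalise bin counts to log2 ratios
#'
#' Counts are scaled by the median over informative bins and
#' log2-transformed, so that the modal (assumed diploid) state sits at 0.
#' Zero-count bins are set to missing by default (they carry no signal and
#' a log of zero would fabricate deep deletions at low depth); the
#' pseudocount mode adds `pseudocount` to every bin instead, which is the
#' appropriate choice when true homozygous deletions are expected to be
#' resolvable. An optional GC correction divides counts by a smoothed
#' median count per GC-content decile before the median scaling.
#'
#' @param counts Integer vector of per-bin counts.
#' @param zero_handling `"missing"` (default) or `"pseudocount"`.
#' @param pseudocount Value added in pseudocount mode (default 0.5).
#' @param gc Optional numeric vector of per-bin GC fractions (same length
#'   as `counts`) enabling GC-decile correction.
#' @return Numeric vector of log2 ratios (`NA` for missing bins).
#' @export
normalize_counts <- function(counts, zero_handling = c("missing", "pseudocount"),
                             pseudocount = 0.5, gc = NULL) {
  zero_handling <- match.arg(zero_handling)
  if (all(counts == 0)) stop("all bins have zero counts", call. = FALSE)
  x <- as.numeric(counts)
  if (zero_handling == "pseudocount") x <- x + pseudocount
  if (!is.null(gc)) {
    stopifnot(length(gc) == length(x))
    dec <- cut(gc, breaks = quantile(gc, probs = seq(0, 1, 0.1), na.rm = TRUE),
               include.lowest = TRUE)
    med <- tapply(x[x > 0], dec[x > 0], median)
    overall <- median(x[x > 0])
    fac <- as.numeric(med[dec]) / overall
    fac[is.na(fac) | fac <= 0] <- 1
    x <- x / fac
  }
  pos <- x > 0
  ratio <- x / median(x[pos])
  out <- rep(NA_real_, length(x))
  out[pos] <- log2(ratio[pos])
  out
}

#' Per-bin GC content of a genome
#'
#' @param genome A `DNAStringSet` (or FASTA path / character vector).
#' @param grid A [bin_grid()].
#' @return Numeric vector of GC fractions per bin.
#' @export
bin_gc <- function(genome, grid) {
  genome <- as_genome(genome)
  out <- rep(NA_real_, nrow(grid))
  for (chr in unique(grid$chrom)) {
    gsel <- which(grid$chrom == chr)
    v <- Biostrings::Views(genome[[chr]], start = grid$start[gsel],
                           end = grid$end[gsel])
    f <- Biostrings::letterFrequency(v, letters = c("GC"), as.prob = TRUE)
    out[gsel] <- as.numeric(f)
  }
  out
}
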