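#' Generate a random synthetic genome
#'
#' Chromosome sequences are i.i.d. bases with the requested GC fraction
#' (C and G each drawn with probability `gc/2`). Deterministic given
#' `seed`.
#'
#' @param lengths Named integer vector of chromosome lengths in bp; names
#'   become chromosome names (defaults to `chr1`, `chr2`, ...).
#' @param gc GC fraction in (0, 1); default 0.41, about that of the human
#'   genome.
#' @param seed Integer random seed.
#' @return A named `DNAStringSet` with attributes `gc` and `seed`.
#' @examples
#' g <- sim_genome(c(chr1 = 5e4), gc = 0.5, seed = 1)
#' @export
sim_genome <- function(lengths, gc = 0.41, seed = 1L) {
  if (!is.numeric(lengths) || length(lengths) == 0L || any(lengths <= 0)) {
    stop("`lengths` must be positive chromosome lengths", call. = FALSE)
  }
  if (!is.numeric(gc) || length(gc) != 1L || gc <= 0 || gc >= 1) {
    stop("`gc` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  set.seed(seed)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(n) {
    paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(lengths)
  attr(g, "gc") <- gc
  attr(g, "seed") <- seed
  g
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet` (or anything [site_index()] accepts).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Define a ground-truth copy-number landscape
#'
#' Validates a per-sample set of non-overlapping integer copy-number
#' intervals that must tile each declared chromosome completely. These
#' intervals are the ground truth a simulation is generated from and the
#' reference that profile recovery is scored against.
#'
#' @param intervals `data.frame` with columns `sample`, `chrom`, `start`,
#'   `end` (1-based inclusive) and `copy` (integer >= 0).
#' @param chrom_lengths Named vector of chromosome lengths the intervals
#'   must cover.
#' @return A `data.table` of class `copy_number_truth`.
#' @export
copy_number_truth <- function(intervals, chrom_lengths) {
  x <- data.table::as.data.table(intervals)
  stopifnot(all(c("sample", "chrom", "start", "end", "copy") %in% names(x)))
  if (any(x$copy < 0) || any(x$copy != round(x$copy))) {
    stop("copy numbers must be non-negative integers", call. = FALSE)
  }
  data.table::setorder(x, sample, chrom, start)
  for (s in unique(x$sample)) {
    for (chr in names(chrom_lengths)) {
      xi <- x[x$sample == s & x$chrom == chr]
      if (nrow(xi) == 0L || xi$start[1] != 1L ||
          xi$end[nrow(xi)] != chrom_lengths[[chr]] ||
          (nrow(xi) > 1L && any(xi$start[-1] != xi$end[-nrow(xi)] + 1L))) {
        stop(sprintf("truth intervals for sample %s must tile %s exactly", s, chr),
             call. = FALSE)
      }
    }
  }
  data.table::setattr(x, "class", c("copy_number_truth", class(x)))
  x[]
}

#' Simulate a random block copy-number landscape
#'
#' Draws, for each sample, contiguous blocks whose copy numbers are sampled
#' from `copies` on a diploid background; block boundaries are aligned to
#' `block_align` bp.
#'
#' @param chrom_lengths Named chromosome lengths.
#' @param samples Sample names.
#' @param n_blocks Number of altered blocks per sample and chromosome.
#' @param copies Candidate copy numbers for altered blocks.
#' @param block_align Boundary alignment in bp (e.g. the bin size).
#' @param block_size Block size in multiples of `block_align` (length-2
#'   range, sampled uniformly).
#' @param seed Integer random seed.
#' @return A [copy_number_truth()].
#' @export
sim_copy_number <- function(chrom_lengths, samples, n_blocks = 3L,
                            copies = c(0L, 1L, 3L, 4L), block_align = 5e4,
                            block_size = c(4L, 10L), seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (s in samples) {
    for (chr in names(chrom_lengths)) {
      len <- chrom_lengths[[chr]]
      n_units <- floor(len / block_align)
      state <- rep(2L, n_units)
      for (b in seq_len(n_blocks)) {
        w <- sample(seq(block_size[1], block_size[2]), 1L)
        if (w >= n_units) next
        at <- sample(n_units - w, 1L)
        if (any(state[at:(at + w - 1L)] != 2L)) next   # keep blocks disjoint
        state[at:(at + w - 1L)] <- sample(copies, 1L)
      }
      r <- rle(state)
      ends_u <- cumsum(r$lengths)
      starts <- c(1L, head(ends_u, -1L) * as.integer(block_align) + 1L)
      ends <- ends_u * as.integer(block_align)
      ends[length(ends)] <- len
      rows[[length(rows) + 1L]] <- data.table::data.table(
        sample = s, chrom = chr, start = starts, end = ends, copy = r$values)
    }
  }
  copy_number_truth(data.table::rbindlist(rows), chrom_lengths)
}

# Copy number of the truth interval containing each position (one sample,
# one chromosome).
copy_at <- function(truth, s, chr, pos) {
  ti <- truth[truth$sample == s & truth$chrom == chr]
  data.table::setorder(ti, start)
  ti$copy[findInterval(pos, ti$start)]
}
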