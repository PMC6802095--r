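#' Amplification/deletion calling thresholds
#'
#' The fixed thresholds on segmented log2 ratios: a segment is called
#' amplified above `log2(2.5/2)` (about +0.322, i.e. half a copy gained on
#' a diploid background) and deleted below `log2(1.5/2)` (about -0.415,
#' half a copy lost).
#'
#' @param amp_log2 Amplification threshold (default `log2(2.5/2)`).
#' @param del_log2 Deletion threshold (default `log2(1.5/2)`).
#' @return Named list of class `call_thresholds`.
#' @export
call_thresholds <- function(amp_log2 = log2(2.5 / 2), del_log2 = log2(1.5 / 2)) {
  stopifnot(del_log2 < 0, 0 < amp_log2)
  structure(list(amp_log2 = amp_log2, del_log2 = del_log2),
            class = "call_thresholds")
}

#' Ternary copy-number calls from segmented values
#'
#' `+1` (amplified) when the segmented log2 ratio exceeds the
#' amplification threshold, `-1` (deleted) below the deletion threshold,
#' `0` (neutral) otherwise. Missing bins are called 0 and flagged in the
#' `missing` attribute.
#'
#' @param segmented Numeric vector of segmented log2 ratios.
#' @param thresholds A [call_thresholds()].
#' @return Integer vector in `{-1, 0, +1}` with logical attribute
#'   `missing`.
#' @export
call_states <- function(segmented, thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  out <- integer(length(segmented))
  out[!is.na(segmented) & segmented > thresholds$amp_log2] <- 1L
  out[!is.na(segmented) & segmented < thresholds$del_log2] <- -1L
  attr(out, "missing") <- is.na(segmented)
  out
}

#' Build a copy-number profile for one sample
#'
#' Runs the profiling stack: per-bin molecule counts, median-normalised
#' log2 ratios (optionally GC-corrected), circular binary segmentation and
#' ternary calling with the fixed thresholds.
#'
#' @param molecules A `molecule_table`; rows of other samples are dropped.
#' @param grid A [bin_grid()].
#' @param sample Sample name (defaults to the single sample present).
#' @param alpha,n_perm,seed Passed to [segment_cbs()].
#' @param zero_handling,pseudocount,gc Passed to [normalize_counts()].
#' @param thresholds A [call_thresholds()].
#' @return An object of class `cn_profile`: `sample`, `bins` (a
#'   `data.table` with `bin`, `chrom`, `start`, `end`, `count`, `log2`,
#'   `segmented`, `call`), `segments`, `thresholds`, `grid`.
#' @export
cn_profile <- function(molecules, grid, sample = NULL, alpha = 0.01,
                       n_perm = 1000L, seed = 1L,
                       zero_handling = "missing", pseudocount = 0.5,
                       gc = NULL, thresholds = call_thresholds()) {
  stopifnot(inherits(grid, "bin_grid"))
  if (is.null(sample)) {
    sample <- unique(molecules$sample)
    if (length(sample) != 1L) {
      stop("`molecules` holds several samples; name one with `sample`", call. = FALSE)
    }
  }
  rows <- which(molecules[["sample"]] == sample)
  m <- molecules[rows]
  counts <- bin_counts(m, grid)
  lr <- normalize_counts(counts, zero_handling = zero_handling,
                         pseudocount = pseudocount, gc = gc)
  seg <- segment_cbs(lr, chrom = grid$chrom, alpha = alpha, n_perm = n_perm,
                     seed = seed)
  calls <- call_states(seg$segmented, thresholds)
  bins <- data.table::data.table(
    bin = grid$bin, chrom = grid$chrom, start = grid$start, end = grid$end,
    count = as.integer(counts), log2 = lr, segmented = seg$segmented,
    call = as.integer(calls))
  structure(list(sample = sample, bins = bins, segments = seg$segments,
                 thresholds = thresholds, grid = grid),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s: %d bins (%d missing), %d segments, %.1f%% aneuploid\n",
              x$sample, nrow(x$bins), sum(is.na(x$bins$segmented)),
              nrow(x$segments), aneuploid_fraction(x)))
  invisible(x)
}

profile_bins <- function(x) {
  if (inherits(x, "cn_profile")) x$bins else data.table::as.data.table(x)
}

#' Signal fluctuation of a profile
#'
#' Mean and population SD of the absolute difference between the
#' non-segmented and segmented log2 ratios over non-missing bins; a
#' depth-sensitive measure of profile noise.
#'
#' @param profile A [cn_profile()] (or its `bins` table).
#' @return Named vector `c(mean, sd)`.
#' @export
fluctuation <- function(profile) {
  b <- profile_bins(profile)
  d <- abs(b$log2 - b$segmented)
  d <- d[!is.na(d)]
  c(mean = mean(d), sd = pop_sd(d))
}

#' Aneuploid genome fraction
#'
#' Percentage of (non-missing) bins called either amplified or deleted.
#'
#' @param x A [cn_profile()], its `bins` table, or a vector of calls with
#'   a `missing` attribute as returned by [call_states()].
#' @return Percentage in `[0, 100]`.
#' @export
aneuploid_fraction <- function(x) {
  if (inherits(x, "cn_profile") || is.data.frame(x)) {
    b <- profile_bins(x)
    calls <- b$call
    miss <- is.na(b$segmented)
  } else {
    calls <- x
    miss <- attr(x, "missing") %||% rep(FALSE, length(x))
  }
  calls <- calls[!miss]
  if (length(calls) == 0L) return(NA_real_)
  100 * sum(calls != 0L) / length(calls)
}

#' Pearson correlation between two profiles
#'
#' Correlation of the per-bin log2 ratios of two profiles on the same bin
#' grid, over bins non-missing in both. Defaults to the segmented values.
#'
#' @param a,b [cn_profile()] objects sharing one grid.
#' @param on `"segmented"` (default) or `"raw"`.
#' @return Pearson correlation (`NA` with a warning when fewer than 3
#'   shared informative bins exist or either side is constant).
#' @export
profile_correlation <- function(a, b, on = c("segmented", "raw")) {
  on <- match.arg(on)
  ba <- profile_bins(a); bb <- profile_bins(b)
  stopifnot(nrow(ba) == nrow(bb))
  va <- if (on == "segmented") ba$segmented else ba$log2
  vb <- if (on == "segmented") bb$segmented else bb$log2
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3L) {
    warning("fewer than 3 shared informative bins; correlation undefined")
    return(NA_real_)
  }
  if (pop_sd(va[ok]) == 0 || pop_sd(vb[ok]) == 0) {
    warning("constant profile; correlation undefined")
    return(NA_real_)
  }
  cor(va[ok], vb[ok])
}

#' Lengths of amplified or deleted genomic segments
#'
#' Merges adjacent bins sharing the requested call state within each
#' chromosome and reports the genomic length of each maximal run.
#'
#' @param profile A [cn_profile()] (or its `bins` table).
#' @param state `"amp"` or `"del"`.
#' @return Numeric vector of lengths in bp (empty when no bin is in the
#'   state).
#' @export
segment_length_distribution <- function(profile, state = c("amp", "del")) {
  state <- match.arg(state)
  want <- if (state == "amp") 1L else -1L
  b <- profile_bins(profile)
  out <- numeric(0)
  for (chr in unique(b$chrom)) {
    bi <- b[b$chrom == chr]
    r <- rle(bi$call == want)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values)) {
      out <- c(out, bi$end[ends[s]] - bi$start[starts[s]] + 1)
    }
  }
  out
}
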