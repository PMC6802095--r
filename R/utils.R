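#' @importFrom stats median rpois rbinom runif cor wilcox.test hclust dist as.dendrogram sd quantile setNames aggregate lm coef
#' @importFrom utils head tail read.table write.table combn
#' @import data.table
NULL

# Population SD (divide by n). Used for all descriptive "mean +/- SD"
# summaries in the package; see the methods vignette.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Hamming distance between equal-length strings; N (or any non-ACGT
# character) counts as a mismatch against everything, including itself.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  bad <- !(av %in% c("A", "C", "G", "T")) | !(bv %in% c("A", "C", "G", "T"))
  sum(av != bv | bad)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorised Hamming distance of many strings against one pattern of the
# same width. Positions carrying non-ACGT characters always mismatch.
hamming_to <- function(strings, pattern) {
  w <- nchar(pattern)
  out <- integer(length(strings))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (i in seq_len(w)) {
    ci <- substr(strings, i, i)
    out <- out + as.integer(ci != pat[i] | !(ci %in% c("A", "C", "G", "T")) |
                              !(pat[i] %in% c("A", "C", "G", "T")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
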