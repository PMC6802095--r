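#' Sequencing error rate from alignment-operation summaries
#'
#' `100 * (deletions + insertions + mismatches) / aligned bases`, pooled
#' over all reads.
#'
#' @param summaries `data.table`/`data.frame` with columns
#'   `aligned_bases`, `mismatches` and optionally `insertions`,
#'   `deletions` (e.g. the output of [anchor_reads()] or [anchor_sam()]),
#'   or a named numeric vector with those totals.
#' @return Error rate as a percentage (`NA` with a warning when no bases
#'   are aligned).
#' @examples
#' error_rate(c(aligned_bases = 100, insertions = 1, deletions = 0, mismatches = 1))
#' @export
error_rate <- function(summaries) {
  if (is.numeric(summaries)) {
    tot <- function(x) if (x %in% names(summaries)) summaries[[x]] else 0
    aligned <- tot("aligned_bases")
    bad <- tot("mismatches") + tot("insertions") + tot("deletions")
  } else {
    aligned <- sum(summaries$aligned_bases, na.rm = TRUE)
    bad <- sum(summaries$mismatches, na.rm = TRUE) +
      sum(summaries$insertions %||% 0, na.rm = TRUE) +
      sum(summaries$deletions %||% 0, na.rm = TRUE)
  }
  if (aligned <= 0) {
    warning("no aligned bases; error rate undefined")
    return(NA_real_)
  }
  100 * bad / aligned
}

#' Per-position base composition of UMIs
#'
#' A library prepared with properly randomised UMIs shows a balanced
#' distribution of all four bases at every UMI position.
#'
#' @param umis Character vector of equal-length UMI sequences.
#' @return Matrix (positions x A,C,G,T) of base fractions; rows sum to 1
#'   when no non-ACGT characters are present.
#' @export
umi_base_composition <- function(umis) {
  if (length(umis) == 0L) stop("no UMIs supplied", call. = FALSE)
  w <- nchar(umis[1])
  out <- matrix(0, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
  for (p in seq_len(w)) {
    cp <- substr(umis, p, p)
    out[p, ] <- vapply(BASES, function(b) mean(cp == b), numeric(1))
  }
  out
}

#' Watson-strand fraction of a molecule table
#'
#' Even partitioning of molecules between the Watson and Crick strands
#' (fraction near 0.5) is a hallmark of clean cut-site-anchored libraries.
#'
#' @param molecules A `molecule_table` from [dedup_umis()].
#' @return Fraction of molecules on the Watson (+) strand.
#' @export
strand_partition <- function(molecules) {
  if (nrow(molecules) == 0L) stop("empty molecule table", call. = FALSE)
  sum(molecules$molecules[molecules$strand == "+"]) / sum(molecules$molecules)
}
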