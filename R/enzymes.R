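#' Restriction enzyme definition
#'
#' Describes a restriction endonuclease by its recognition sequence and the
#' position of the top-strand cut. The two built-in enzymes are the
#' methylation-insensitive cutters used for reduced-representation
#' library preparation: NlaIII (`CATG`, a four-base cutter leaving a 4-nt
#' 3' overhang) and HindIII (`AAGCTT`, a six-base cutter leaving a 4-nt
#' 5' overhang). Both are palindromic, so the bottom-strand cut offset is
#' `nchar(recognition) - cut_offset_top`.
#'
#' Degenerate IUPAC codes are not supported: the recognition sequence must
#' be an exact string over A/C/G/T.
#'
#' @param name Short identifier, e.g. `"NlaIII"`.
#' @param recognition Recognition sequence over A,C,G,T (case-insensitive).
#' @param cut_offset_top Integer offset of the top-strand cut, counted in
#'   bases from the start of the recognition sequence (0 = cut before the
#'   first base). NlaIII cuts `CATG^` (offset 4); HindIII cuts `A^AGCTT`
#'   (offset 1).
#' @param overhang_len Length of the single-stranded overhang left by the
#'   cut. Must equal `abs(2 * cut_offset_top - nchar(recognition))` for a
#'   palindromic enzyme.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("NlaIII", "CATG", 4, 4)
#' enzyme("HindIII")
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top, overhang_len) {
  recognition <- toupper(recognition)
  if (!grepl("^[ACGT]+$", recognition)) {
    stop("recognition sequence must be an exact string over A/C/G/T; ",
         "degenerate IUPAC codes are not supported", call. = FALSE)
  }
  len <- nchar(recognition)
  check_scalar_number(cut_offset_top, "cut_offset_top", 0, len)
  check_scalar_number(overhang_len, "overhang_len", 0, len)
  if (overhang_len != abs(2 * cut_offset_top - len)) {
    stop("overhang_len inconsistent with cut_offset_top for a palindromic site",
         call. = FALSE)
  }
  cut_offset_bottom <- len - cut_offset_top
  structure(
    list(name = name, recognition = recognition,
         cut_offset_top = as.integer(cut_offset_top),
         cut_offset_bottom = as.integer(cut_offset_bottom),
         overhang_len = as.integer(overhang_len),
         palindromic = recognition == revcomp(recognition)),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s (top cut %d, bottom cut %d, %d-nt overhang)\n",
              x$name, x$recognition, x$cut_offset_top, x$cut_offset_bottom,
              x$overhang_len))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' @param name `"NlaIII"` or `"HindIII"` (case-insensitive).
#' @return A [restriction_enzyme()].
#' @export
enzyme <- function(name) {
  switch(tolower(name),
    nlaiii  = restriction_enzyme("NlaIII", "CATG", 4L, 4L),
    hindiii = restriction_enzyme("HindIII", "AAGCTT", 1L, 4L),
    stop("unknown built-in enzyme: ", name,
         "; define it with restriction_enzyme()", call. = FALSE)
  )
}

# 1-based coordinate of the first genomic base of a read anchored on the
# Watson (+) / Crick (-) strand of a site whose recognition starts at `p`.
# For a palindromic enzyme both reads begin with the same sequence on their
# own strand.
watson_anchor <- function(p, enz) p + min(enz$cut_offset_top, enz$cut_offset_bottom)
crick_anchor  <- function(p, enz) p + max(enz$cut_offset_top, enz$cut_offset_bottom) - 1L

#' Scan a sequence for restriction recognition sites
#'
#' Finds all occurrences (including overlapping ones) of an enzyme's
#' recognition sequence. Matching is case-insensitive; windows containing
#' `N` are never reported as sites.
#'
#' @param sequence A nucleotide string over A,C,G,T,N (any case), or a
#'   `Biostrings::DNAString`.
#' @param enz A [restriction_enzyme()].
#' @return Sorted integer vector of 1-based recognition-start positions.
#' @examples
#' scan_sites("ACATGCATGT", enzyme("NlaIII"))  # 2, 6
#' @export
scan_sites <- function(sequence, enz) {
  stopifnot(inherits(enz, "restriction_enzyme"))
  if (is.character(sequence)) {
    if (nchar(sequence) == 0L) return(integer(0))
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  if (length(sequence) < nchar(enz$recognition)) return(integer(0))
  m <- Biostrings::matchPattern(enz$recognition, sequence, fixed = TRUE)
  sort(Biostrings::start(m))
}

#' Index all recognition sites of an enzyme in a genome
#'
#' @param genome A named `DNAStringSet`, a named character vector of
#'   chromosome sequences, or a path to a FASTA file.
#' @param enz A [restriction_enzyme()].
#' @param genome_id Optional identifier stored with the index.
#' @return An object of class `site_index`: per-chromosome sorted 1-based
#'   recognition-start positions plus chromosome lengths.
#' @export
site_index <- function(genome, enz, genome_id = "genome") {
  genome <- as_genome(genome)
  sites <- lapply(seq_along(genome), function(i) scan_sites(genome[[i]], enz))
  names(sites) <- names(genome)
  structure(
    list(genome_id = genome_id, enzyme = enz, sites = sites,
         chrom_lengths = setNames(Biostrings::width(genome), names(genome))),
    class = "site_index"
  )
}

#' @export
print.site_index <- function(x, ...) {
  cat(sprintf("<site_index> %s / %s: %d sites on %d chromosome(s)\n",
              x$genome_id, x$enzyme$name, sum(lengths(x$sites)),
              length(x$sites)))
  invisible(x)
}

# Coerce character vector / file path / DNAStringSet to a named DNAStringSet.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  stopifnot(inherits(genome, "DNAStringSet"))
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  genome
}
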