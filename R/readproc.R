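#' Validate a sample-barcode whitelist
#'
#' @param barcodes Named character vector (sample -> 8-nt barcode) or a
#'   `data.frame` with columns `sample` and `barcode` (see
#'   [read_whitelist()]).
#' @param min_dist Minimum pairwise Hamming distance expected between
#'   barcodes (default 5, so that two-mismatch assignment is unambiguous).
#'   Violations produce a warning, not an error.
#' @return Named character vector of validated barcodes.
#' @export
barcode_whitelist <- function(barcodes, min_dist = 5L) {
  if (is.data.frame(barcodes)) {
    stopifnot(all(c("sample", "barcode") %in% names(barcodes)))
    barcodes <- setNames(toupper(barcodes$barcode), barcodes$sample)
  } else {
    barcodes <- setNames(toupper(barcodes), names(barcodes))
  }
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    stop("every barcode needs a sample name", call. = FALSE)
  }
  if (any(nchar(barcodes) != 8L)) stop("barcodes must be 8 nt long", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("barcodes must be unique", call. = FALSE)
  if (anyDuplicated(names(barcodes))) stop("sample names must be unique", call. = FALSE)
  if (length(barcodes) > 1L) {
    pd <- combn(barcodes, 2L, function(p) hamming(p[1], p[2]))
    if (min(pd) < min_dist) {
      warning(sprintf("minimum pairwise barcode Hamming distance is %d (< %d); ",
                      min(pd), min_dist),
              "two-mismatch demultiplexing may reject reads as ambiguous")
    }
  }
  barcodes
}

#' Parse the UMI + barcode prefix off raw reads
#'
#' Reads are expected to start with an 8-nt UMI followed by an 8-nt sample
#' barcode; the remainder is the genomic insert. Reads shorter than
#' `16 + min_insert` are rejected (categorised, not an error).
#'
#' @param seqs Character vector of read sequences, or the `data.table`
#'   returned by [read_fastq()].
#' @param min_insert Minimum insert length in nt (default 20).
#' @return `data.table` with `read_id`, `umi`, `barcode`, `insert` and
#'   `reject` (`NA` for parsed reads, `"too_short"` otherwise).
#' @examples
#' parse_prefix("AAAAAAAACCCCCCCCACGTACGTACGTACGTACGTACGT")
#' @export
parse_prefix <- function(seqs, min_insert = 20L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$read_id
    seqs <- seqs$seq
  } else {
    ids <- paste0("read", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  ok <- nchar(seqs) >= PREFIX_LEN + min_insert
  data.table::data.table(
    read_id = ids,
    umi = ifelse(ok, substr(seqs, 1L, UMI_LEN), NA_character_),
    barcode = ifelse(ok, substr(seqs, UMI_LEN + 1L, PREFIX_LEN), NA_character_),
    insert = ifelse(ok, substring(seqs, PREFIX_LEN + 1L), NA_character_),
    reject = ifelse(ok, NA_character_, "too_short"))
}

#' Assign raw barcodes to whitelist samples
#'
#' Each raw barcode is assigned to the unique whitelist entry within
#' Hamming distance `max_mismatch`. `N` (or any non-ACGT base) counts as a
#' mismatch. Ties -- two whitelist entries at the same minimal distance
#' within tolerance -- are rejected as ambiguous rather than resolved at
#' random, which prevents sample bleed-through.
#'
#' @param raw Character vector of observed 8-nt barcodes.
#' @param whitelist A [barcode_whitelist()] (named character vector).
#' @param max_mismatch Maximum tolerated Hamming distance (default 2).
#' @return `data.table` with `sample` (`NA` when unassigned), `distance`
#'   (to the best entry) and `status` (`assigned`, `unassigned`,
#'   `ambiguous`).
#' @export
assign_barcode <- function(raw, whitelist, max_mismatch = 2L) {
  whitelist <- barcode_whitelist(whitelist)
  raw <- toupper(raw)
  D <- vapply(whitelist, function(bc) hamming_to(raw, bc),
              integer(length(raw)))
  if (length(raw) == 1L) D <- matrix(D, nrow = 1L)
  best <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_along(raw), best)]
  n_at_min <- rowSums(D == dmin)
  status <- rep("assigned", length(raw))
  status[dmin > max_mismatch] <- "unassigned"
  status[dmin <= max_mismatch & n_at_min > 1L] <- "ambiguous"
  data.table::data.table(
    sample = ifelse(status == "assigned", names(whitelist)[best], NA_character_),
    distance = dmin,
    status = status)
}

#' Down-sample reads or molecules
#'
#' Keeps each record independently with probability `fraction`;
#' deterministic given `seed`. Mirrors read down-sampling used to compare
#' profiles across sequencing depths.
#'
#' @param x A `data.frame`/`data.table` (rows are records) or a vector.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer random seed.
#' @return Subset of `x` of the same type.
#' @export
downsample <- function(x, fraction, seed = 1L) {
  check_scalar_number(fraction, "fraction", lower = 1e-12, upper = 1)
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (fraction == 1) return(x)
  set.seed(seed)
  keep <- runif(n) < fraction
  if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
}
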