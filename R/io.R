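#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; the returned table uses the package's
#' internal 1-based inclusive convention. The optional 4th BED column
#' becomes `name`.
#'
#' @param path BED file path.
#' @return `data.table` with `chrom`, `start`, `end` and (when present)
#'   `name`.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    df <- as.data.frame(rtracklayer::import(path, format = "BED"))
    out <- data.table::data.table(
      chrom = as.character(df$seqnames), start = df$start, end = df$end)
    if ("name" %in% names(df)) out[, name := df$name]
    return(out[])
  }
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.table::data.table(chrom = x[[1]], start = x[[2]] + 1L, end = x[[3]])
  if (ncol(x) >= 4L) out[, name := x[[4]]]
  out[]
}

#' Write genomic intervals to a BED file
#'
#' @param x `data.frame` with `chrom`, `start`, `end` (1-based inclusive)
#'   and optional further columns (`name`, `score`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end)
  for (col in setdiff(names(x), c("chrom", "start", "end"))) out[[col]] <- x[[col]]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample-barcode whitelist from TSV
#'
#' Expects two columns, `sample` and `barcode` (header optional).
#'
#' @param path TSV path.
#' @return Validated named barcode vector (see [barcode_whitelist()]).
#' @export
read_whitelist <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("sample", "barcode"),
                  header = FALSE, comment.char = "#")
  if (tolower(x$sample[1]) == "sample") x <- x[-1L, , drop = FALSE]
  barcode_whitelist(setNames(x$barcode, x$sample))
}

#' Write a table (molecule table, profile bins, ...) as TSV
#'
#' @param x A `data.frame`/`data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}
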