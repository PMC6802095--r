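#' Distances between consecutive recognition sites
#'
#' Computes the distribution of distances between consecutive
#' recognition-start positions, within chromosomes only (never across a
#' chromosome boundary), and summarises it as mean, population SD and
#' median. This is the statistic used to compare the genome-wide cutting
#' frequency and homogeneity of candidate enzymes (for the human genome,
#' roughly 210 bp for NlaIII vs 3.4 kb for HindIII).
#'
#' @param index A [site_index()].
#' @return A list with `distances` (pooled integer vector), `summary`
#'   (mean, sd, median, n) and `defined` (FALSE when no chromosome has at
#'   least two sites).
#' @export
intersite_distances <- function(index) {
  stopifnot(inherits(index, "site_index"))
  d <- unlist(lapply(index$sites, function(p) if (length(p) >= 2L) diff(p) else integer(0)),
              use.names = FALSE)
  if (length(d) == 0L) {
    return(list(distances = integer(0),
                summary = c(mean = NA_real_, sd = NA_real_, median = NA_real_, n = 0),
                defined = FALSE))
  }
  list(distances = d,
       summary = c(mean = mean(d), sd = pop_sd(d), median = median(d), n = length(d)),
       defined = TRUE)
}

#' Bin-wise homogeneity of recognition-site spacing
#'
#' Tiles each chromosome with non-overlapping windows of `bin_size` bp and
#' reports, per window, the population SD of the distances between
#' consecutive sites whose left member falls in the window. Windows with
#' fewer than two sites get `NA`. A small SD across most windows indicates
#' a homogeneously cutting enzyme.
#'
#' @param index A [site_index()].
#' @param bin_size Window size in bp (default 100 kb).
#' @return A `data.table` with columns `chrom`, `start`, `end`, `n_sites`,
#'   `sd_distance`.
#' @export
binwise_homogeneity <- function(index, bin_size = 1e5) {
  stopifnot(inherits(index, "site_index"))
  check_scalar_number(bin_size, "bin_size", lower = 1)
  res <- lapply(names(index$sites), function(chr) {
    len <- index$chrom_lengths[[chr]]
    starts <- seq(1L, len, by = as.integer(bin_size))
    ends <- pmin(starts + as.integer(bin_size) - 1L, len)
    p <- index$sites[[chr]]
    bin_of <- findInterval(p, starts)            # bin of each site
    n_sites <- tabulate(bin_of, nbins = length(starts))
    sdv <- rep(NA_real_, length(starts))
    if (length(p) >= 2L) {
      d <- diff(p)
      left_bin <- bin_of[-length(bin_of)]        # distance assigned to left site's bin
      for (b in unique(left_bin)) {
        db <- d[left_bin == b]
        if (length(db) >= 1L && n_sites[b] >= 2L) sdv[b] <- pop_sd(db)
      }
    }
    data.table::data.table(chrom = chr, start = starts, end = ends,
                           n_sites = n_sites, sd_distance = sdv)
  })
  data.table::rbindlist(res)
}

#' Recognition-site density in genomic regions
#'
#' Expands each region by `shift` bp on both sides (clamped to the
#' chromosome), counts recognition sites inside the expanded region and
#' divides by its length in kb. Used to ask how many cut sites fall inside
#' (or within reach of) exons of genes of interest; the outward shift
#' models reads that reach a region from a nearby cut site.
#'
#' @param index A [site_index()].
#' @param regions `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based, inclusive) and optionally `name`. See [read_bed()].
#' @param shift Outward expansion in bp applied to both ends (default 50).
#' @return A list with `regions` (the input plus `n_sites`, `eff_length_bp`
#'   and `sites_per_kb`) and `summary` (mean, median, population SD of the
#'   per-region densities).
#' @export
region_site_density <- function(index, regions, shift = 50) {
  stopifnot(inherits(index, "site_index"))
  regions <- data.table::as.data.table(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(regions$start <= regions$end))
  check_scalar_number(shift, "shift", lower = 0)
  unknown <- setdiff(unique(regions$chrom), names(index$sites))
  if (length(unknown) > 0L) {
    stop("regions refer to chromosome(s) absent from the site index: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- data.table::copy(regions)
  lo <- pmax(1L, as.integer(out$start - shift))
  hi <- pmin(index$chrom_lengths[out$chrom], as.integer(out$end + shift))
  n <- integer(nrow(out))
  for (chr in unique(out$chrom)) {
    idx <- which(out$chrom == chr)
    p <- index$sites[[chr]]
    # sites with recognition start inside [lo, hi]
    n[idx] <- findInterval(hi[idx], p) - findInterval(lo[idx] - 1L, p)
  }
  out[, `:=`(n_sites = n, eff_length_bp = hi - lo + 1L)]
  out[, sites_per_kb := n_sites / (eff_length_bp / 1000)]
  list(regions = out[],
       summary = c(mean = mean(out$sites_per_kb),
                   median = median(out$sites_per_kb),
                   sd = pop_sd(out$sites_per_kb)))
}

#' Distance from genomic points to the nearest recognition site
#'
#' For each point, the minimum absolute distance to any recognition-start
#' position on the same chromosome. Points on chromosomes without any site
#' get `NA`.
#'
#' @param points `data.frame` with columns `chrom` and `pos` (1-based).
#' @param index A [site_index()].
#' @return A list with `distance` (vector aligned with `points`) and
#'   `summary` (mean, population SD, median over defined distances).
#' @export
distance_to_nearest_site <- function(points, index) {
  stopifnot(inherits(index, "site_index"),
            all(c("chrom", "pos") %in% names(points)))
  unknown <- setdiff(unique(points$chrom), names(index$sites))
  if (length(unknown) > 0L) {
    stop("points refer to chromosome(s) absent from the site index: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- rep(NA_real_, nrow(points))
  for (chr in unique(points$chrom)) {
    idx <- which(points$chrom == chr)
    p <- index$sites[[chr]]
    if (length(p) == 0L) next
    pos <- points$pos[idx]
    k <- findInterval(pos, p)
    left <- ifelse(k >= 1L, pos - p[pmax(k, 1L)], Inf)
    right <- ifelse(k < length(p), p[pmin(k + 1L, length(p))] - pos, Inf)
    d[idx] <- pmin(left, right)
  }
  ok <- !is.na(d)
  list(distance = d,
       summary = c(mean = if (any(ok)) mean(d[ok]) else NA_real_,
                   sd = if (any(ok)) pop_sd(d[ok]) else NA_real_,
                   median = if (any(ok)) median(d[ok]) else NA_real_,
                   n = sum(ok)))
}
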