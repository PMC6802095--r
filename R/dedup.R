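#' Collapse PCR duplicates by UMI
#'
#' Groups reads by (chromosome, anchored site, strand, sample) and counts
#' original molecules per group. Two methods are provided:
#'
#' * `exact`: the number of distinct UMI sequences in the group.
#' * `directional` (default): an adjacency-network collapse. Within a
#'   group, a directed edge `u -> v` connects UMIs at Hamming distance 1
#'   with `count(u) >= 2 * count(v) - 1`. Nodes are visited in decreasing
#'   read-count order (ties broken lexicographically); each unvisited node
#'   seeds a new molecule and absorbs every node reachable along directed
#'   edges. The molecule count is the number of seeds. This mirrors the
#'   default directional method of common UMI-collapsing tools and is
#'   robust to substitution errors in duplicate UMIs.
#'
#' The exact count is always greater than or equal to the directional
#' count.
#'
#' @param reads `data.table` with columns `chrom`, `site`, `strand`,
#'   `sample`, `umi` (one row per read; typically anchored, filtered reads
#'   joined with their parsed prefix).
#' @param method `"directional"` (default) or `"exact"`.
#' @return A `molecule_table`: `data.table` with `chrom`, `site`,
#'   `strand`, `sample`, `molecules`.
#' @export
dedup_umis <- function(reads, method = c("directional", "exact")) {
  method <- match.arg(method)
  reads <- data.table::as.data.table(reads)
  stopifnot(all(c("chrom", "site", "strand", "sample", "umi") %in% names(reads)))
  umi_counts <- reads[, .(n = .N), by = .(chrom, site, strand, sample, umi)]
  if (method == "exact") {
    out <- umi_counts[, .(molecules = .N), by = .(chrom, site, strand, sample)]
    return(as_molecule_table(out))
  }
  umi_counts[, gid := .GRP, by = .(chrom, site, strand, sample)]
  pairs <- hamming1_pairs(umi_counts)
  simple <- umi_counts[!gid %in% pairs$gid,
                       .(molecules = .N), by = .(chrom, site, strand, sample, gid)]
  if (nrow(pairs) > 0L) {
    cplx_gids <- unique(pairs$gid)
    by_gid_nodes <- split(umi_counts[gid %in% cplx_gids], by = "gid")
    by_gid_pairs <- split(pairs, by = "gid")
    cplx <- data.table::rbindlist(lapply(names(by_gid_nodes), function(g) {
      nodes <- by_gid_nodes[[g]]
      m <- directional_components(nodes$umi, nodes$n, by_gid_pairs[[g]])
      nodes[1L, .(chrom, site, strand, sample, gid, molecules = m)]
    }))
    out <- rbind(simple, cplx)
  } else {
    out <- simple
  }
  out[, gid := NULL]
  as_molecule_table(out)
}

# All within-group unordered UMI pairs at Hamming distance exactly 1,
# found by masking one position at a time and self-joining.
hamming1_pairs <- function(umi_counts) {
  w <- nchar(umi_counts$umi[1])
  res <- list()
  for (p in seq_len(w)) {
    masked <- paste0(substr(umi_counts$umi, 1L, p - 1L),
                     substring(umi_counts$umi, p + 1L))
    dt <- data.table::data.table(gid = umi_counts$gid, umi = umi_counts$umi,
                                 key_ = masked)
    m <- merge(dt, dt, by = c("gid", "key_"), allow.cartesian = TRUE,
               suffixes = c("_a", "_b"))
    m <- m[m$umi_a < m$umi_b]
    if (nrow(m) > 0L) res[[length(res) + 1L]] <- m[, .(gid, umi_a, umi_b)]
  }
  if (length(res) == 0L) {
    return(data.table::data.table(gid = integer(0), umi_a = character(0),
                                  umi_b = character(0)))
  }
  unique(data.table::rbindlist(res))
}

# Directional cluster count for one group: umis/counts plus the group's
# Hamming-1 pair list (may be NULL).
directional_components <- function(umis, counts, pairs) {
  k <- length(umis)
  ord <- order(-counts, umis)
  adj <- vector("list", k)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    ia <- match(pairs$umi_a, umis)
    ib <- match(pairs$umi_b, umis)
    for (e in seq_along(ia)) {
      a <- ia[e]; b <- ib[e]
      if (counts[a] >= 2L * counts[b] - 1L) adj[[a]] <- c(adj[[a]], b)
      if (counts[b] >= 2L * counts[a] - 1L) adj[[b]] <- c(adj[[b]], a)
    }
  }
  visited <- logical(k)
  n_clusters <- 0L
  for (v in ord) {
    if (visited[v]) next
    n_clusters <- n_clusters + 1L
    stack <- v
    visited[v] <- TRUE
    while (length(stack) > 0L) {
      cur <- stack[[1L]]
      stack <- stack[-1L]
      nxt <- adj[[cur]]
      nxt <- nxt[!visited[nxt]]
      visited[nxt] <- TRUE
      stack <- c(stack, nxt)
    }
  }
  n_clusters
}

as_molecule_table <- function(x) {
  data.table::setorder(x, sample, chrom, site, strand)
  data.table::setattr(x, "class", c("molecule_table", class(x)))
  x[]
}

#' Tabulate truth molecules in the same shape as [dedup_umis()] output
#'
#' @param sim A [sim_molecules()] result.
#' @return A `molecule_table` with the ground-truth molecule counts.
#' @export
truth_molecule_table <- function(sim) {
  stopifnot(inherits(sim, "simulation_truth"))
  out <- sim$molecules[, .(molecules = sum(count)),
                       by = .(chrom, site, strand, sample)]
  as_molecule_table(out)
}
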