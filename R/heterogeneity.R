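#' Gene-level copy-number states across samples
#'
#' For every gene and profile, the state (+1 amplified / 0 neutral / -1
#' deleted) of the called region overlapping the largest fraction of the
#' gene. When a non-neutral and the neutral state tie exactly on overlap,
#' the non-neutral state wins; when +1 and -1 tie, the state is 0 and the
#' (gene, sample) pair is flagged as conflicting. Genes overlapping no bin
#' get `NA` with a warning.
#'
#' @param profiles Named list of [cn_profile()] objects sharing one grid.
#' @param genes `data.frame` with `chrom`, `start`, `end` (1-based,
#'   inclusive) and `name`.
#' @return An integer matrix (genes x samples) of class
#'   `gene_state_matrix` with a logical `conflict` attribute of the same
#'   shape.
#' @export
gene_states <- function(profiles, genes) {
  stopifnot(length(profiles) >= 1L,
            all(c("chrom", "start", "end", "name") %in% names(genes)))
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(p) p$sample, character(1))
  }
  grid <- profiles[[1]]$grid
  M <- matrix(NA_integer_, nrow = nrow(genes), ncol = length(profiles),
              dimnames = list(genes$name, names(profiles)))
  conflict <- matrix(FALSE, nrow = nrow(genes), ncol = length(profiles),
                     dimnames = dimnames(M))
  for (gi in seq_len(nrow(genes))) {
    gsel <- which(grid$chrom == genes$chrom[gi] &
                    grid$end >= genes$start[gi] & grid$start <= genes$end[gi])
    if (length(gsel) == 0L) {
      warning("gene ", genes$name[gi], " overlaps no bin; state missing")
      next
    }
    ow <- pmin(grid$end[gsel], genes$end[gi]) -
      pmax(grid$start[gsel], genes$start[gi]) + 1
    for (si in seq_along(profiles)) {
      calls <- profiles[[si]]$bins$call[gsel]
      by_state <- tapply(ow, calls, sum)
      best <- max(by_state)
      winners <- as.integer(names(by_state)[by_state == best])
      if (length(winners) == 1L) {
        M[gi, si] <- winners
      } else if (any(winners != 0L)) {
        nz <- winners[winners != 0L]
        if (length(nz) == 1L) {
          M[gi, si] <- nz                       # non-neutral beats neutral
        } else {
          M[gi, si] <- 0L                       # +1 vs -1: conflict
          conflict[gi, si] <- TRUE
        }
      } else {
        M[gi, si] <- 0L
      }
    }
  }
  structure(M, conflict = conflict, class = c("gene_state_matrix", "matrix", "array"))
}

#' Rank genes by recurrence of a state
#'
#' Orders genes by the number of samples in which they are amplified (or
#' deleted); ties are broken lexicographically by gene name.
#'
#' @param matrix A [gene_states()] matrix.
#' @param state `"amp"` or `"del"`.
#' @return `data.table` with `gene` and `n_samples`, descending.
#' @export
recurrence_ranking <- function(matrix, state = c("amp", "del")) {
  state <- match.arg(state)
  want <- if (state == "amp") 1L else -1L
  counts <- apply(unclass(matrix), 1L, function(r) sum(r == want, na.rm = TRUE))
  out <- data.table::data.table(gene = rownames(matrix), n_samples = counts)
  data.table::setorder(out, -n_samples, gene)
  out[]
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Clusters samples by the Euclidean distance between their gene-state
#' vectors (or per-bin profile values), followed by complete-linkage
#' agglomeration via [stats::hclust()]. In multi-region tumour data,
#' replicate libraries of one region are expected to merge first and
#' regions of a metastasis to cluster apart from the primary lesion.
#'
#' @param x A [gene_states()] matrix (genes x samples), or a named list of
#'   [cn_profile()] objects (clustered on their segmented log2 ratios over
#'   bins informative in every profile).
#' @param on For profile input: `"segmented"` (default) or `"raw"`.
#' @return An [stats::hclust()] object; samples with no usable values are
#'   excluded with a warning.
#' @export
cluster_samples <- function(x, on = c("segmented", "raw")) {
  on <- match.arg(on)
  if (inherits(x, "gene_state_matrix") || (is.matrix(x) && !is.null(rownames(x)))) {
    V <- t(unclass(x))                          # samples x genes
  } else if (is.list(x)) {
    if (is.null(names(x))) names(x) <- vapply(x, function(p) p$sample, character(1))
    vals <- vapply(x, function(p) {
      b <- profile_bins(p)
      if (on == "segmented") b$segmented else b$log2
    }, numeric(nrow(profile_bins(x[[1]]))))
    keep_bins <- rowSums(is.na(vals)) == 0L
    V <- t(vals[keep_bins, , drop = FALSE])
  } else {
    stop("unsupported input for cluster_samples()", call. = FALSE)
  }
  usable <- rowSums(!is.na(V)) > 0L
  if (!all(usable)) {
    warning("excluding sample(s) with all-missing values: ",
            paste(rownames(V)[!usable], collapse = ", "))
    V <- V[usable, , drop = FALSE]
  }
  if (nrow(V) < 2L) stop("need at least 2 samples to cluster", call. = FALSE)
  hclust(dist(V, method = "euclidean"), method = "complete")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An [stats::hclust()] object.
#' @param path Optional file path to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Concordance between replicate profile pairs
#'
#' For each replicate pair, the fraction of the genome called amplified
#' and the fraction called deleted in either member; across pairs, the
#' Pearson correlation (amplified and deleted points pooled, and also per
#' state) and the least-squares slope of member B on member A.
#'
#' @param pairs List of two-element lists/vectors of [cn_profile()]
#'   objects: `list(list(A1, B1), list(A2, B2), ...)`.
#' @return A list with `table` (per pair and state: `fraction_a`,
#'   `fraction_b`), `pearson` (pooled), `pearson_by_state`, `slope`.
#'   Correlations over constant fractions are `NA` with a warning.
#' @export
replicate_concordance <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  rows <- lapply(seq_along(pairs), function(i) {
    a <- pairs[[i]][[1]]; b <- pairs[[i]][[2]]
    frac <- function(p, want) {
      bb <- profile_bins(p)
      ok <- !is.na(bb$segmented)
      if (!any(ok)) return(NA_real_)
      100 * sum(bb$call[ok] == want) / sum(ok)
    }
    data.table::data.table(
      pair = i, state = c("amp", "del"),
      fraction_a = c(frac(a, 1L), frac(a, -1L)),
      fraction_b = c(frac(b, 1L), frac(b, -1L)))
  })
  tab <- data.table::rbindlist(rows)
  ok <- !is.na(tab$fraction_a) & !is.na(tab$fraction_b)
  pooled <- NA_real_
  slope <- NA_real_
  if (sum(ok) >= 2L && pop_sd(tab$fraction_a[ok]) > 0 && pop_sd(tab$fraction_b[ok]) > 0) {
    pooled <- cor(tab$fraction_a[ok], tab$fraction_b[ok])
    slope <- unname(coef(lm(tab$fraction_b[ok] ~ tab$fraction_a[ok]))[2])
  } else {
    warning("constant or insufficient fractions; pooled correlation undefined")
  }
  by_state <- vapply(c("amp", "del"), function(s) {
    ts <- tab[tab$state == s & ok]
    if (nrow(ts) >= 2L && pop_sd(ts$fraction_a) > 0 && pop_sd(ts$fraction_b) > 0) {
      cor(ts$fraction_a, ts$fraction_b)
    } else NA_real_
  }, numeric(1))
  list(table = tab, pearson = pooled, pearson_by_state = by_state, slope = slope)
}

#' Compare CNA burden between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, e.g. comparing the
#' aneuploid genome fractions of metastatic vs primary tumour regions
#' among samples with detectable CNAs. The exact null distribution is
#' used for small untied samples, the normal approximation with tie
#' correction otherwise (the standard [stats::wilcox.test()] switch).
#'
#' @param a,b Numeric vectors (each with at least one value).
#' @return List with `U` (statistic for group `a`) and `p_value`.
#' @export
burden_comparison <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = unname(wt$p.value))
}
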