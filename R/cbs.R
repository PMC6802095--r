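#' Circular binary segmentation of log2 ratios
#'
#' Recursive change-point detection: within the current interval, the arc
#' `(i, j]` of the circularised series maximising the absolute two-sample
#' t-statistic between in-arc and out-of-arc bins is located by exhaustive
#' search; its significance is assessed by a permutation test (values
#' shuffled within the interval); if significant at level `alpha` the
#' interval is split at the arc boundaries and the procedure recurses,
#' otherwise one segment is emitted. Chromosomes are segmented
#' independently; missing bins are excluded and rejoin their chromosome's
#' segments as gaps. The segmented value of a bin is the arithmetic mean
#' of the raw log2 ratios of its segment, which is the least-squares value
#' given the breakpoints.
#'
#' @param log2_ratio Numeric vector of per-bin log2 ratios (`NA` allowed).
#' @param chrom Chromosome of each bin (same length); segmentation never
#'   crosses a chromosome boundary.
#' @param alpha Significance level of the permutation test (default 0.01).
#' @param n_perm Number of permutations (default 1000).
#' @param min_width Minimum number of bins in an arc (default 2).
#' @param seed Integer random seed for the permutation test (mandatory for
#'   reproducible segmentations).
#' @return A list with `segmented` (per-bin segmented values, `NA` where
#'   the input was missing) and `segments` (`data.table`: `chrom`,
#'   `start_bin`, `end_bin`, `n_bins`, `mean` -- bin indices refer to the
#'   input vector).
#' @export
segment_cbs <- function(log2_ratio, chrom = rep("chr1", length(log2_ratio)),
                        alpha = 0.01, n_perm = 1000L, min_width = 2L,
                        seed = 1L) {
  stopifnot(length(chrom) == length(log2_ratio))
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  set.seed(seed)
  segmented <- rep(NA_real_, length(log2_ratio))
  seg_rows <- list()
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    obs <- sel[!is.na(log2_ratio[sel])]
    if (length(obs) == 0L) next
    x <- log2_ratio[obs]
    bk <- cbs_recurse(x, alpha, n_perm, min_width)    # sorted split points
    bounds <- c(0L, bk, length(x))
    for (s in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      m <- mean(x[idx])
      segmented[obs[idx]] <- m
      seg_rows[[length(seg_rows) + 1L]] <- data.table::data.table(
        chrom = chr, start_bin = obs[idx[1L]], end_bin = obs[idx[length(idx)]],
        n_bins = length(idx), mean = m)
    }
  }
  list(segmented = segmented,
       segments = if (length(seg_rows)) data.table::rbindlist(seg_rows)
                  else data.table::data.table(chrom = character(0),
                                              start_bin = integer(0),
                                              end_bin = integer(0),
                                              n_bins = integer(0),
                                              mean = numeric(0)))
}

# Recursive splitter: returns sorted internal breakpoints (split after
# position b) of the series x.
cbs_recurse <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < 2L * min_width) return(integer(0))
  sp <- cbs_best_arc(x, min_width)
  if (is.null(sp)) return(integer(0))
  p <- cbs_perm_p(x, sp$tmax, n_perm, min_width)
  if (p >= alpha) return(integer(0))
  cuts <- setdiff(c(sp$i, sp$j), c(0L, n))
  if (length(cuts) == 0L) return(integer(0))
  bounds <- c(0L, sort(cuts), n)
  out <- sort(cuts)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s] + 1L; hi <- bounds[s + 1L]
    sub <- cbs_recurse(x[lo:hi], alpha, n_perm, min_width)
    out <- c(out, bounds[s] + sub)
  }
  sort(unique(out))
}

# Exhaustive max-|t| circular arc (i, j], min_width <= j-i <= n-min_width.
# Returns list(i, j, tmax) or NULL when no admissible arc exists.
cbs_best_arc <- function(x, min_width = 2L) {
  n <- length(x)
  pr <- arc_pairs(n, min_width)
  if (is.null(pr)) return(NULL)
  t <- arc_tstat(matrix(x, nrow = 1L), pr)
  best <- which.max(abs(t[1L, ]))
  list(i = pr$i[best], j = pr$j[best], tmax = abs(t[1L, best]))
}

# Admissible arc boundary pairs for a series of length n.
arc_pairs <- function(n, min_width) {
  if (n < 2L * min_width) return(NULL)
  i <- rep(0L:(n - 1L), times = n:1L)
  j <- unlist(lapply(0L:(n - 1L), function(a) (a + 1L):n))
  k <- j - i
  keep <- k >= min_width & k <= n - min_width
  if (!any(keep)) return(NULL)
  list(i = i[keep], j = j[keep], k = k[keep])
}

# Two-sample t-statistics of arcs (i, j] vs complement for each row of X.
# X: m x n matrix; pr: arc_pairs(n, .). Returns m x P matrix.
arc_tstat <- function(X, pr) {
  n <- ncol(X)
  cs <- cbind(0, t(apply(X, 1L, cumsum)))
  if (nrow(X) == 1L) cs <- matrix(cs, nrow = 1L)
  tot <- cs[, n + 1L]
  ss <- rowSums(X^2)
  SA <- cs[, pr$j + 1L, drop = FALSE] - cs[, pr$i + 1L, drop = FALSE]
  k <- pr$k
  m1 <- sweep(SA, 2L, k, "/")
  m2 <- sweep(-SA, 1L, tot, `+`)
  m2 <- sweep(m2, 2L, n - k, "/")
  s2 <- (ss - sweep(m1^2, 2L, k, "*") - sweep(m2^2, 2L, n - k, "*")) / (n - 2L)
  s2[s2 < 0] <- 0
  se <- sqrt(sweep(s2, 2L, 1 / k + 1 / (n - k), "*"))
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  t[se == 0 & m1 != m2] <- Inf * sign((m1 - m2)[se == 0 & m1 != m2])
  t
}

# Permutation p-value for the observed max |t|, with add-one correction.
cbs_perm_p <- function(x, tmax_obs, n_perm, min_width) {
  n <- length(x)
  pr <- arc_pairs(n, min_width)
  if (is.null(pr)) return(1)
  exceed <- 0L
  block <- 100L
  done <- 0L
  while (done < n_perm) {
    m <- min(block, n_perm - done)
    P <- t(vapply(seq_len(m), function(...) sample(x), numeric(n)))
    tm <- apply(abs(arc_tstat(P, pr)), 1L, max)
    exceed <- exceed + sum(tm >= tmax_obs)
    done <- done + m
  }
  (1 + exceed) / (1 + n_perm)
}
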