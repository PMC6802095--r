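# Independent brute-force oracles. These deliberately avoid the package's
# optimised code paths: plain loops, full enumeration, no shared helpers.

# sliding-window occurrence scan (overlapping matches, N never matches)
naive_scan <- function(sequence, pattern) {
  sequence <- toupper(sequence)
  w <- nchar(pattern)
  hits <- integer(0)
  if (nchar(sequence) < w) return(hits)
  for (i in seq_len(nchar(sequence) - w + 1L)) {
    if (substr(sequence, i, i + w - 1L) == pattern) hits <- c(hits, i)
  }
  hits
}

naive_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv | !(av %in% c("A", "C", "G", "T")) | !(bv %in% c("A", "C", "G", "T")))
}

# exhaustive nearest-site distance
brute_nearest <- function(pos, sites) {
  if (length(sites) == 0L) return(NA_real_)
  min(abs(sites - pos))
}

# exhaustive barcode assignment
brute_assign <- function(raw, whitelist, max_mismatch = 2L) {
  d <- vapply(whitelist, function(b) naive_hamming(raw, b), integer(1))
  m <- min(d)
  if (m > max_mismatch) return(NA_character_)
  if (sum(d == m) > 1L) return(NA_character_)
  names(whitelist)[which.min(d)]
}

# directional UMI collapse, written from the rule definition: edge u->v if
# Hamming(u,v)==1 and count(u) >= 2*count(v)-1; visit nodes by decreasing
# count (lexicographic tie-break); each unvisited node seeds a cluster and
# absorbs everything reachable along directed edges.
brute_directional <- function(umis, counts) {
  k <- length(umis)
  reach <- matrix(FALSE, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b && naive_hamming(umis[a], umis[b]) == 1L &&
        counts[a] >= 2L * counts[b] - 1L) reach[a, b] <- TRUE
  }
  ord <- order(-counts, umis)
  visited <- logical(k)
  clusters <- 0L
  for (v in ord) {
    if (visited[v]) next
    clusters <- clusters + 1L
    frontier <- v
    visited[v] <- TRUE
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(u) which(reach[u, ] & !visited))))
      visited[nxt] <- TRUE
      frontier <- nxt
    }
  }
  clusters
}

# exhaustive max-|t| circular arc for a short series
brute_best_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- NULL
  for (i in 0:(n - 1L)) for (j in (i + 1L):n) {
    k <- j - i
    if (k < min_width || k > n - min_width) next
    arc <- x[(i + 1L):j]
    rest <- x[setdiff(seq_len(n), (i + 1L):j)]
    sp <- ((length(arc) - 1L) * var(arc) + (length(rest) - 1L) * var(rest)) / (n - 2L)
    if (length(arc) == 1L) sp <- ((length(rest) - 1L) * var(rest)) / (n - 2L)
    se <- sqrt(sp * (1 / k + 1 / (n - k)))
    t <- if (se == 0) 0 else abs(mean(arc) - mean(rest)) / se
    if (is.null(best) || t > best$t) best <- list(i = i, j = j, t = t)
  }
  best
}

# complete-linkage agglomeration by direct simulation; returns the
# cophenetic distance matrix (height at which each pair first co-clusters)
brute_complete_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(D[clusters[[a]], clusters[[b]]])
      if (is.null(best) || h < best$h) best <- list(a = a, b = b, h = h)
    }
    for (i in clusters[[best$a]]) for (j in clusters[[best$b]]) {
      coph[i, j] <- coph[j, i] <- best$h
    }
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  coph
}

# exact two-sided Mann-Whitney by enumeration of all group assignments
brute_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  us <- apply(combs, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu))
  list(U = u_obs, p_value = min(1, p))
}

# binomial 3-SD tolerance around expected proportion p with n trials
binom_tol <- function(p, n, k = 3) k * sqrt(p * (1 - p) / n)

# truth-derived ternary call for an integer copy number on diploid background
truth_call <- function(copy) ifelse(copy == 2L, 0L, ifelse(copy > 2L, 1L, -1L))
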