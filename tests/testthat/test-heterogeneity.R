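# minimal hand-built profile: calls per 100-kb bin on one chromosome
mk_profile <- function(calls, sample = "S", grid = NULL) {
  n <- length(calls)
  if (is.null(grid)) grid <- bin_grid(c(chr1 = n * 1e5), bin_size = 1e5)
  seg <- as.numeric(calls) * 0.6
  bins <- data.table::data.table(
    bin = grid$bin, chrom = grid$chrom, start = grid$start, end = grid$end,
    count = 10L, log2 = seg, segmented = seg, call = as.integer(calls))
  structure(list(sample = sample, bins = bins,
                 segments = data.table::data.table(),
                 thresholds = call_thresholds(), grid = grid),
            class = "cn_profile")
}

test_that("gene states take the dominant overlapping call with documented ties", {
  profiles <- list(P1 = mk_profile(c(1, 1, 0, 0, -1, -1)),
                   P2 = mk_profile(c(0, 0, 0, 0, 0, 0)))
  genes <- data.frame(chrom = "chr1",
                      start = c(1, 250001, 150001),
                      end = c(150000, 420000, 250000),
                      name = c("gAmp", "gNeu", "gTie"))
  gs <- gene_states(profiles, genes)
  expect_equal(gs["gAmp", "P1"], 1L)       # amplified in 1.5 of 1.5 bins
  expect_equal(gs["gNeu", "P1"], 0L)       # mostly neutral
  # exact tie non-neutral vs neutral (50 kb each): non-neutral wins
  expect_equal(gs["gTie", "P1"], 1L)
  expect_true(all(gs[, "P2"] == 0L))
  # +1/-1 exact tie -> 0 with conflict flag
  pc <- list(P = mk_profile(c(1, -1, 0)))
  gconf <- gene_states(pc, data.frame(chrom = "chr1", start = 1, end = 200000,
                                      name = "gConf"))
  expect_equal(gconf["gConf", "P"], 0L)
  expect_true(attr(gconf, "conflict")["gConf", "P"])
  expect_warning(gene_states(profiles, data.frame(chrom = "chr9", start = 1,
                                                  end = 10, name = "off")),
                 "overlaps no bin")
})

test_that("gene states match a brute-force per-bin overlap tally", {
  set.seed(81)
  calls <- sample(c(-1L, 0L, 1L), 40, replace = TRUE)
  prof <- list(P = mk_profile(calls))
  starts <- sample(39e5, 30)
  genes <- data.frame(chrom = "chr1", start = starts,
                      end = pmin(starts + sample(c(5e4, 2e5, 5e5), 30,
                                                 replace = TRUE), 40e5),
                      name = sprintf("g%02d", 1:30))
  gs <- gene_states(prof, genes)
  grid <- prof$P$grid
  for (i in seq_len(nrow(genes))) {
    ov <- numeric(3); names(ov) <- c("-1", "0", "1")
    for (b in seq_len(nrow(grid))) {
      w <- min(grid$end[b], genes$end[i]) - max(grid$start[b], genes$start[i]) + 1
      if (w > 0) ov[as.character(calls[b])] <- ov[as.character(calls[b])] + w
    }
    top <- names(ov)[ov == max(ov)]
    want <- if (length(top) == 1L) as.integer(top)
            else if (all(c("-1", "1") %in% top)) 0L
            else as.integer(setdiff(top, "0"))
    expect_equal(unname(gs[genes$name[i], "P"]), want)
  }
})

test_that("recurrence ranking counts samples per state with lexicographic ties", {
  profiles <- list(A = mk_profile(c(1, 1, 0, -1)), B = mk_profile(c(1, 0, 0, -1)),
                   C = mk_profile(c(1, 0, 0, 0)))
  genes <- data.frame(chrom = "chr1", start = c(1, 100001, 300001),
                      end = c(100000, 200000, 400000),
                      name = c("zeta", "alpha", "delta"))
  gs <- gene_states(profiles, genes)
  rk <- recurrence_ranking(gs, "amp")
  expect_equal(rk$gene, c("zeta", "alpha", "delta"))
  expect_equal(rk$n_samples, c(3L, 1L, 0L))
  expect_equal(sum(rk$n_samples), sum(unclass(gs) == 1L))
  rkd <- recurrence_ranking(gs, "del")
  expect_equal(rkd$n_samples[rkd$gene == "delta"], 2L)
  # all-neutral matrix ranks everything at zero
  gs0 <- gene_states(list(A = mk_profile(rep(0, 4))), genes)
  expect_true(all(recurrence_ranking(gs0, "amp")$n_samples == 0L))
})

test_that("identical samples merge first and trees match a hand trace", {
  m <- matrix(c(1, 0, -1, 1,
                1, 0, -1, 1,
                -1, 1, 0, 0), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("r1", "r2", "far")))
  class(m) <- c("gene_state_matrix", "matrix", "array")
  hc <- cluster_samples(m)
  expect_equal(hc$merge[1, ], c(-1L, -2L))        # the twins merge at height 0
  expect_equal(hc$height[1], 0)
  # 3-point hand trace: d(a,b)=1, d(a,c)=2, d(b,c)=2.5 -> (a,b) at 1, then c at 2.5
  D <- matrix(c(0, 1, 2, 1, 0, 2.5, 2, 2.5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc2 <- hclust(as.dist(D), method = "complete")
  expect_equal(hc2$height, c(1, 2.5))
  expect_equal(sort(hc2$merge[1, ]), c(-2L, -1L))
})

test_that("complete linkage equals exhaustive agglomeration for small sample sets", {
  set.seed(82)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    V <- matrix(rnorm(n * 5), nrow = n,
                dimnames = list(paste0("s", seq_len(n)), NULL))
    m <- t(V); rownames(m) <- paste0("g", 1:5)
    hc <- cluster_samples(m)
    got <- as.matrix(stats::cophenetic(hc))
    D <- as.matrix(dist(V))
    want <- brute_complete_linkage_cophenetic(D)
    dimnames(want) <- dimnames(D)
    expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-12)
  }
})

test_that("dendrograms export as Newick with sample labels", {
  m <- matrix(rnorm(12), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("s1", "s2", "s3")))
  hc <- cluster_samples(m)
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(c("s1", "s2", "s3"), grepl, logical(1), x = nwk)))
  f <- tempfile(fileext = ".nwk")
  dendrogram_newick(hc, f)
  expect_identical(readLines(f), nwk)
})

test_that("replicate concordance is perfect for identical profiles", {
  set.seed(83)
  ps <- lapply(1:4, function(i) mk_profile(sample(c(-1L, 0L, 1L), 20,
                                                  replace = TRUE,
                                                  prob = c(.2, .6, .2))))
  pairs <- lapply(ps, function(p) list(p, p))
  rc <- replicate_concordance(pairs)
  expect_equal(rc$pearson, 1)
  expect_equal(rc$slope, 1, tolerance = 1e-9)
  expect_true(all(rc$table$fraction_a == rc$table$fraction_b))
  # constant fractions across pairs -> undefined, flagged
  same <- mk_profile(rep(0, 20))
  expect_warning(rc0 <- replicate_concordance(list(list(same, same),
                                                   list(same, same))),
                 "undefined")
  expect_true(is.na(rc0$pearson))
})

test_that("Mann-Whitney burden comparison matches exhaustive enumeration", {
  r <- burden_comparison(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 0.1)              # 2/20 arrangements as extreme
  same <- burden_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  set.seed(84)
  for (rep in 1:20) {
    a <- round(runif(sample(2:6, 1)) * 100)
    b <- round(runif(sample(2:6, 1)) * 100)
    if (anyDuplicated(c(a, b))) next        # enumeration oracle assumes no ties
    got <- burden_comparison(a, b)
    want <- brute_mann_whitney(a, b)
    expect_equal(unname(got$U), want$U)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})
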