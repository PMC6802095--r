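test_that("bin grids tile autosomes and counts are conserved", {
  grid <- bin_grid(c(chr1 = 250000, chrX = 100000), bin_size = 1e5)
  expect_equal(nrow(grid), 3L)                       # chrX excluded
  expect_equal(grid$end[3], 250000L)                 # short last bin
  mt <- data.table::data.table(chrom = "chr1", site = c(10L, 20L, 150000L),
                               strand = "+", sample = "A", molecules = 1L)
  counts <- bin_counts(mt, grid)
  expect_equal(as.integer(counts), c(2L, 1L, 0L))
  expect_equal(sum(counts), sum(mt$molecules))
  empty <- bin_counts(mt[0], grid)
  expect_equal(as.integer(empty), c(0L, 0L, 0L))
  expect_warning(bin_counts(data.table::data.table(
    chrom = "chr9", site = 1L, strand = "+", sample = "A", molecules = 2L),
    grid), "outside")
})

test_that("normalisation centres the median and maps ratios to log2", {
  expect_equal(normalize_counts(c(4, 4, 4, 4)), rep(0, 4))
  lr <- normalize_counts(c(4, 4, 8, 4, 4))
  expect_equal(lr[3], 1.0)
  # zero bins missing by default, pseudocount mode keeps them
  lr0 <- normalize_counts(c(0, 4, 4, 4))
  expect_true(is.na(lr0[1]))
  lrp <- normalize_counts(c(0, 4, 4, 4), zero_handling = "pseudocount")
  expect_false(any(is.na(lrp)))
  expect_lt(lrp[1], -3)
  expect_error(normalize_counts(c(0, 0)), "zero")
})

test_that("CBS finds an induced breakpoint and stays quiet on null data", {
  set.seed(61)
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
  s <- segment_cbs(x, seed = 62)
  expect_equal(nrow(s$segments), 2L)
  expect_true(abs(s$segments$end_bin[1] - 50L) <= 1L)
  # segmented value is the arithmetic mean of member bins, exactly
  for (r in seq_len(nrow(s$segments))) {
    idx <- s$segments$start_bin[r]:s$segments$end_bin[r]
    expect_equal(unique(s$segmented[idx]), mean(x[idx]))
  }
  x0 <- rnorm(60, 0, 0.1)
  s0 <- segment_cbs(x0, seed = 63)
  expect_equal(nrow(s0$segments), 1L)
  # chromosomes segment independently
  s2 <- segment_cbs(c(x, x0), chrom = rep(c("chr1", "chr2"), c(100, 60)), seed = 64)
  expect_true(all(s2$segments$chrom[1:2] == "chr1"))
  expect_equal(sum(s2$segments$chrom == "chr2"), 1L)
  # intervals shorter than 2 bins yield one trivial segment
  s3 <- segment_cbs(c(0.5), seed = 65)
  expect_equal(nrow(s3$segments), 1L)
})

test_that("the first CBS split equals the exhaustive max-t arc", {
  set.seed(66)
  for (rep in 1:25) {
    n <- sample(8:25, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 1, 2), 1)), c(floor(n / 2), ceiling(n / 2)))
    got <- rrcna:::cbs_best_arc(x, min_width = 2L)
    want <- brute_best_arc(x, min_width = 2L)
    expect_equal(got$tmax, want$t, tolerance = 1e-10)
    # arc and complement are the same split; compare induced breakpoints
    expect_identical(setdiff(c(got$i, got$j), c(0L, n)),
                     setdiff(c(want$i, want$j), c(0L, n)))
  }
})

test_that("splitting never increases the residual sum of squares", {
  set.seed(67)
  for (rep in 1:10) {
    x <- rnorm(40) + rep(c(0, 1.5), each = 20)
    s <- segment_cbs(x, seed = rep)
    rss_seg <- sum((x - s$segmented)^2)
    rss_flat <- sum((x - mean(x))^2)
    expect_lte(rss_seg, rss_flat + 1e-12)
  }
})

test_that("ternary calls apply the half-copy thresholds and are monotone", {
  th <- call_thresholds()
  expect_equal(th$amp_log2, log2(2.5 / 2))
  expect_equal(th$del_log2, log2(1.5 / 2))
  calls <- call_states(c(0.33, -0.50, 0.0, NA), th)
  expect_equal(as.integer(calls), c(1L, -1L, 0L, 0L))
  expect_equal(attr(calls, "missing"), c(FALSE, FALSE, FALSE, TRUE))
  # monotone: increasing a segmented value never moves a call downward
  gridv <- seq(-1, 1, by = 0.01)
  cv <- as.integer(call_states(gridv, th))
  expect_true(all(diff(cv) >= 0))
})

test_that("fluctuation and aneuploid fraction summarise profiles correctly", {
  b <- data.table::data.table(
    bin = 1:10, chrom = "chr1", start = 1, end = 2,
    count = 1L, log2 = c(rep(0.1, 5), rep(-0.1, 5)),
    segmented = 0, call = c(1L, 1L, -1L, rep(0L, 7)))
  f <- fluctuation(b)
  expect_equal(unname(f["mean"]), 0.1)
  expect_equal(unname(f["sd"]), 0)
  expect_equal(aneuploid_fraction(b), 30)
  b2 <- data.table::copy(b)[, `:=`(log2 = segmented)]
  expect_equal(unname(fluctuation(b2)["mean"]), 0)
  b3 <- data.table::copy(b)[, call := 0L]
  expect_equal(aneuploid_fraction(b3), 0)
  b4 <- data.table::copy(b)[, call := 1L]
  expect_equal(aneuploid_fraction(b4), 100)
})

test_that("profile correlation is 1 for identical and -1 for mirrored profiles", {
  mk <- function(v) data.table::data.table(
    bin = seq_along(v), chrom = "chr1", start = 1, end = 2, count = 1L,
    log2 = v, segmented = v, call = 0L)
  v <- c(0.2, -0.3, 0.5, 0.1, -0.4)
  expect_equal(profile_correlation(mk(v), mk(v)), 1)
  expect_equal(profile_correlation(mk(v), mk(-v)), -1)
  expect_warning(r <- profile_correlation(mk(v[1:2]), mk(v[1:2])), "fewer than 3")
  expect_true(is.na(r))
})

test_that("segment length runs merge within chromosomes and respect identity", {
  b <- data.table::data.table(
    bin = 1:10, chrom = rep(c("chr1", "chr2"), each = 5),
    start = rep(seq(1, 4e5 + 1, 1e5), 2), end = rep(seq(1e5, 5e5, 1e5), 2),
    count = 1L, log2 = 0, segmented = 0,
    call = c(1L, 1L, 1L, 0L, -1L, 1L, 0L, 0L, -1L, -1L))
  amp <- segment_length_distribution(b, "amp")
  expect_equal(sort(amp), c(1e5, 3e5))
  del <- segment_length_distribution(b, "del")
  expect_equal(sort(del), c(1e5, 2e5))
  none <- segment_length_distribution(data.table::copy(b)[, call := 0L], "amp")
  expect_length(none, 0)
  # lengths sum equals aneuploid fraction times covered genome
  covered <- sum(b$end - b$start + 1)
  expect_equal(sum(amp) + sum(del), aneuploid_fraction(b) / 100 * covered)
})

test_that("cn_profile recovers an amplification from simulated molecules", {
  fix <- small_sim_fixture()
  rr <- sim_reads(fix$sim, fix$barcodes, pcr_dup_mean = 0, subst_error_rate = 0,
                  seed = 71)
  res <- process_reads(rr$reads, fix$genome, fix$enz, fix$barcodes)
  # 10-kb bins: a permutation test at alpha 0.01 needs enough bins per
  # chromosome for contiguous-null arrangements to be rare
  grid <- bin_grid(fix$lengths, bin_size = 1e4)
  pA <- cn_profile(res$molecules, grid, sample = "A", seed = 72)
  # chr1 100-200 kb is copy 4 in sample A: mean log2 near 1
  amp_bins <- pA$bins[chrom == "chr1" & start > 1e5]
  expect_lt(abs(mean(amp_bins$segmented) - 1), 0.2)
  expect_true(all(amp_bins$call == 1L))
  expect_true(all(pA$bins[chrom == "chr1" & end <= 1e5]$call == 0L))
  # sample B: chr2 is copy 1 -> deletion calls
  pB <- cn_profile(res$molecules, grid, sample = "B", seed = 73)
  expect_true(all(pB$bins[chrom == "chr2"]$call == -1L))
  expect_true(all(pB$bins[chrom == "chr1"]$call == 0L))
})
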