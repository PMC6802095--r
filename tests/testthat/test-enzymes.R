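test_that("scan_sites finds all and only recognition-site occurrences", {
  nla <- enzyme("NlaIII")
  expect_equal(scan_sites("ACATGCATGT", nla), c(2L, 6L))
  expect_equal(scan_sites("AAAAAA", nla), integer(0))
  expect_equal(scan_sites("CATGCATG", nla), c(1L, 5L))
  expect_equal(diff(scan_sites("CATGCATG", nla)), 4L)
  expect_equal(scan_sites("", nla), integer(0))
  expect_equal(scan_sites("catgCATG", nla), c(1L, 5L))   # case-insensitive
  expect_equal(scan_sites("CANGCATG", nla), 5L)          # N never matches
})

test_that("scan_sites agrees with a naive sliding-window scan on random inputs", {
  set.seed(11)
  for (enz in list(enzyme("NlaIII"), enzyme("HindIII"))) {
    for (rep in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 400,
                        replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                 collapse = "")
      expect_equal(scan_sites(s, enz), naive_scan(s, enz$recognition))
    }
  }
})

test_that("palindromic recognition yields mirrored sites on the reverse complement", {
  set.seed(12)
  nla <- enzyme("NlaIII")
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fwd <- scan_sites(s, nla)
    rev <- scan_sites(rc, nla)
    # recognition start p on forward maps to n - (p + 4) + 2 on the mirror
    expect_equal(sort(nchar(s) - fwd - nchar(nla$recognition) + 2L), sort(rev))
  }
})

test_that("enzyme definitions validate their geometry", {
  hind <- enzyme("HindIII")
  expect_equal(hind$recognition, "AAGCTT")
  expect_equal(hind$cut_offset_top, 1L)
  expect_true(hind$palindromic)
  expect_error(restriction_enzyme("bad", "CATN", 2, 0), "degenerate|A/C/G/T")
  expect_error(restriction_enzyme("bad", "CATG", 3, 4), "inconsistent")
  expect_error(enzyme("EcoRI"), "unknown")
})

test_that("intersite distances are within-chromosome differences with pooled summary", {
  enz <- enzyme("NlaIII")
  g <- c(chr1 = paste0("A", "CATG", "AAA", "CATG", "AAAAA", "CATG", "AA"),
         chr2 = "CATGAAAA")
  idx <- site_index(g, enz)
  d <- intersite_distances(idx)
  expect_equal(d$distances, c(7L, 9L))          # never across chromosomes
  expect_equal(unname(d$summary["mean"]), 8)
  # sum of per-chromosome distances equals last - first site
  p <- idx$sites$chr1
  expect_equal(sum(diff(p)), p[length(p)] - p[1])
  # fewer than 2 sites everywhere: undefined summary
  e <- intersite_distances(site_index(c(chr1 = "CATGAA"), enz))
  expect_false(e$defined)
  expect_length(e$distances, 0)
})

test_that("bin-wise homogeneity uses the population SD and flags sparse bins", {
  enz <- enzyme("NlaIII")
  # sites at 11, 21, 41 in one bin: distances 10, 20 -> population SD 5
  s <- paste0(strrep("A", 10), "CATG", strrep("A", 6), "CATG",
              strrep("A", 16), "CATG", strrep("A", 60))
  idx <- site_index(c(chr1 = s), enz)
  expect_equal(idx$sites$chr1, c(11L, 21L, 41L))
  h <- binwise_homogeneity(idx, bin_size = 1000)
  expect_equal(h$sd_distance[1], 5)
  # uniformly spaced sites -> SD 0 in full bins
  u <- paste(rep(paste0("CATG", strrep("A", 196)), 50), collapse = "")
  hu <- binwise_homogeneity(site_index(c(chr1 = u), enz), bin_size = 2000)
  expect_true(all(hu$sd_distance[hu$n_sites >= 2] == 0))
  # empty bin -> missing value
  sparse <- paste0("CATGAA", strrep("A", 3000))
  hs <- binwise_homogeneity(site_index(c(chr1 = sparse), enz), bin_size = 1000)
  expect_true(all(is.na(hs$sd_distance)))
})

test_that("region site density expands regions and is invariant to pooled splits", {
  enz <- enzyme("NlaIII")
  s <- paste0(strrep("A", 100), "CATG", "CATG", strrep("A", 92),
              "CATG", strrep("A", 800), "CATG", strrep("A", 96))
  idx <- site_index(c(chr1 = s), enz)
  r <- data.frame(chrom = "chr1", start = 101, end = 1100, name = "r1")
  d0 <- region_site_density(idx, r, shift = 0)
  expect_equal(d0$regions$eff_length_bp, 1000L)
  expect_equal(d0$regions$sites_per_kb, d0$regions$n_sites / 1)
  # 900-bp region with shift 50 -> 1 kb denominator
  r2 <- data.frame(chrom = "chr1", start = 151, end = 1050)
  d2 <- region_site_density(idx, r2, shift = 50)
  expect_equal(d2$regions$eff_length_bp, 1000L)
  # split invariance at shift 0 with pooled counts
  halves <- data.frame(chrom = "chr1", start = c(101, 601), end = c(600, 1100))
  dh <- region_site_density(idx, halves, shift = 0)
  expect_equal(sum(dh$regions$n_sites), d0$regions$n_sites)
  expect_equal(sum(dh$regions$n_sites) / (sum(dh$regions$eff_length_bp) / 1000),
               d0$regions$sites_per_kb)
  expect_error(region_site_density(idx, data.frame(chrom = "chrZ", start = 1, end = 10)),
               "chrZ")
})

test_that("region density on random regions matches genome-wide density", {
  fix <- small_sim_fixture()
  idx <- site_index(fix$genome, fix$enz)
  set.seed(21)
  starts <- sample(1e5, 200)
  r <- data.frame(chrom = "chr1", start = starts, end = starts + 999L)
  d <- region_site_density(idx, r, shift = 0)
  genome_wide <- length(idx$sites$chr1) / (fix$lengths[["chr1"]] / 1000)
  expect_lt(abs(d$summary[["mean"]] - genome_wide), 0.15 * genome_wide)
})

test_that("nearest-site distances match a brute-force scan", {
  enz <- enzyme("NlaIII")
  g <- c(chr1 = paste0(strrep("A", 89), "CATG", strrep("A", 106), "CATG", strrep("A", 50)))
  idx <- site_index(g, enz)
  expect_equal(idx$sites$chr1, c(90L, 200L))
  res <- distance_to_nearest_site(data.frame(chrom = "chr1", pos = c(100, 90, 145)), idx)
  expect_equal(res$distance, c(10, 0, 55))
  set.seed(22)
  pts <- data.frame(chrom = "chr1", pos = sample(240, 50))
  got <- distance_to_nearest_site(pts, idx)$distance
  want <- vapply(pts$pos, brute_nearest, numeric(1), sites = idx$sites$chr1)
  expect_equal(got, want)
  # siteless chromosome -> NA
  idx2 <- site_index(c(chr1 = "CATGAAAA", chr2 = "AAAAAAAA"), enz)
  res2 <- distance_to_nearest_site(data.frame(chrom = "chr2", pos = 3), idx2)
  expect_true(is.na(res2$distance))
})
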