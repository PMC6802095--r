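# Shared small simulation fixture, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_sim_fixture <- function() {
  if (!is.null(.fixture_env$fix)) return(.fixture_env$fix)
  enz <- enzyme("NlaIII")
  lengths <- c(chr1 = 2e5, chr2 = 1e5)
  genome <- sim_genome(lengths, gc = 0.5, seed = 7)
  truth <- copy_number_truth(data.table::data.table(
    sample = rep(c("A", "B"), each = 3),
    chrom = rep(c("chr1", "chr1", "chr2"), 2),
    start = rep(c(1L, 100001L, 1L), 2),
    end = rep(c(100000L, 200000L, 100000L), 2),
    copy = c(2L, 4L, 2L, 2L, 2L, 1L)), lengths)
  sim <- sim_molecules(genome, truth, enz, lambda_per_copy = 2, seed = 3)
  barcodes <- setNames(make_barcodes(2, seed = 9), c("A", "B"))
  .fixture_env$fix <- list(enz = enz, lengths = lengths, genome = genome,
                           truth = truth, sim = sim, barcodes = barcodes)
  .fixture_env$fix
}
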