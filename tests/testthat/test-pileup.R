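test_that("alignment identity follows the exact-match / read-length rule", {
  long <- strrep("A", 20)
  expect_equal(alignment_identity(0, "10M", strrep("A", 10), long), 1.0)
  # 8 matches + 1 mismatch + 1 soft-clipped base over a length-10 read
  expect_equal(alignment_identity(0, "9M1S", "AAAACAAAAG", long), 0.8)
})

test_that("alignment identity matches base-by-base comparison for 50=1X49=", {
  set.seed(5)
  long <- random_bases(150)
  short <- substr(long, 21, 120)
  mism <- substr(short, 51, 51)
  alt <- setdiff(c("A", "C", "G", "T"), mism)[1]
  substr(short, 51, 51) <- alt
  # oracle: explicit comparison over the reconstructed alignment
  matches <- sum(strsplit(short, "")[[1]] ==
                 strsplit(substr(long, 21, 120), "")[[1]])
  expect_equal(alignment_identity(20, "50=1X49=", short, long),
               matches / 100)
  expect_equal(alignment_identity(20, "50=1X49=", short, long), 0.99)
})

test_that("fully agreeing alignments produce no questionable sites", {
  set.seed(9)
  longs <- read_set("L1", random_bases(60))
  aln <- data.table::rbindlist(lapply(1:5, function(i) {
    s <- 5 * i
    aln_row(paste0("s", i), "L1", s, "20M",
            substr(longs$seq, s + 1, s + 20), strrep("I", 20), longs$seq)
  }))
  pl <- build_pileup(aln, longs)
  expect_equal(nrow(pl$sites), 0L)
})

test_that("a single mismatch yields one site with one disagreeing vote", {
  longs <- read_set("L1", "ACGTGACGTG")
  short <- "ACGAGACGTG"   # A instead of T at position 3
  a <- aln_row("s1", "L1", 0, "10M", short, phred_encode(rep(30L, 10)),
               longs$seq)
  pl <- build_pileup(a, longs)
  expect_equal(nrow(pl$sites), 1L)
  site <- site_evidence(pl, "L1", 3)
  expect_equal(site$long_base, "T")
  dis <- site$votes[!site$votes$agree, ]
  expect_equal(nrow(dis), 1L)
  expect_equal(dis$type, "SUB")
  expect_equal(dis$edit, "A")
  expect_equal(dis$q, 30L)
})

test_that("a short-read deletion proposes DELETE at the long-read base", {
  # oracle: manual CIGAR walk on a 7 bp toy pair
  # long  A C G A T T T      (extra A at position 3)
  # short A C G - T T T      3=1D3=
  longs <- read_set("L1", "ACGATTT")
  a <- aln_row("s1", "L1", 0, "3=1D3=", "ACGTTT",
               phred_encode(c(30L, 30L, 20L, 40L, 30L, 30L)), longs$seq)
  pl <- build_pileup(a, longs)
  site <- site_evidence(pl, "L1", 3)
  expect_false(is.null(site))
  dis <- site$votes[!site$votes$agree, ]
  expect_equal(dis$type, "DEL")
  # deletion quality = floored mean of flanking short-read bases (20, 40)
  expect_equal(dis$q, 30L)
})

test_that("a short-read insertion proposes INS at the inter-base locus", {
  # long  A C G - T T T      (missing A between positions 2 and 3)
  # short A C G A T T T      3=1I3=
  longs <- read_set("L1", "ACGTTT")
  a <- aln_row("s1", "L1", 0, "3=1I3=", "ACGATTT",
               phred_encode(rep(35L, 7)), longs$seq)
  pl <- build_pileup(a, longs)
  site <- site_evidence(pl, "L1", 3, is_ins = TRUE)
  expect_false(is.null(site))
  dis <- site$votes[!site$votes$agree, ]
  expect_equal(dis$type, "INS")
  expect_equal(dis$edit, "A")
  expect_equal(dis$q, 35L)
})

test_that("N bases never vote", {
  longs <- read_set("L1", "ACGTGACGTG")
  a <- aln_row("s1", "L1", 0, "10M", "ACGNGACGTG",
               phred_encode(rep(30L, 10)), longs$seq)
  pl <- build_pileup(a, longs)
  expect_equal(nrow(pl$sites), 0L)
})

test_that("error-free simulated data yields zero questionable sites", {
  sim <- simulate_hybrid_data(sim_config(
    reference_length = 4000L, n_long = 4L, long_length = c(800L, 1200L),
    long_error = 0, short_error = 0, coverage = 15, seed = 3L))
  pl <- build_pileup(sim$alignments, sim$long_reads)
  expect_equal(nrow(pl$sites), 0L)
  # and the long reads are exact reference slices
  for (i in seq_along(sim$long_reads$id)) {
    tm <- sim$truth_map[i]
    expect_equal(sim$long_reads$seq[i],
                 substr(sim$reference, tm$ref_start + 1, tm$ref_end))
  }
})

test_that("votes at a site never exceed the covering depth", {
  sim <- small_sim()
  pl <- build_pileup(sim$alignments, sim$long_reads)
  expect_true(nrow(pl$sites) > 0)
  expect_true(all(pl$sites$n_votes <= pl$sites$coverage))
  expect_true(all(pl$sites$coverage >= 1L))
})
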