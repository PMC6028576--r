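test_that("the confidence threshold is the nearest-rank percentile", {
  expect_equal(confidence_threshold(seq(0.01, 1, by = 0.01), 95), 0.95)
  expect_equal(confidence_threshold(0.7, 95), 0.7)
  expect_equal(confidence_threshold(0.7, 5), 0.7)
  # sort-based oracle across sizes and alpha values
  set.seed(31)
  for (n in c(1, 2, 3, 10, 100, 1234, 10000)) {
    costs <- runif(n)
    for (alpha in c(90, 95, 99)) {
      s <- sort(costs)
      oracle <- s[max(1, ceiling(alpha / 100 * n))]
      expect_identical(confidence_threshold(costs, alpha), oracle)
    }
  }
})

test_that("about five percent of corrections clear the 95th-percentile bar", {
  set.seed(202)
  costs <- runif(1000)
  mu <- confidence_threshold(costs, 95)
  frac <- mean(costs >= mu)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.06)
})

test_that("high-confidence splitting applies quick always, optimized by threshold", {
  dec <- data.table::data.table(
    rname = "L1", pos = c(1L, 2L, 3L), is_ins = 0L,
    type = "SUB", edit = "A",
    origin = c("OPTIMIZED", "OPTIMIZED", "QUICK"),
    J = c(0.99, 0.5, NA), winner = "s1", q = 30L)
  sp <- apply_high_confidence(dec, mu = 0.9)
  expect_equal(sp$applied$pos, c(1L, 3L))
  expect_equal(sp$deferred$pos, 2L)
  # all-quick decisions are applied regardless of mu
  dq <- dec[origin == "QUICK"]
  sp2 <- apply_high_confidence(dq, mu = NA_real_)
  expect_equal(nrow(sp2$applied), 1L)
  expect_equal(nrow(sp2$deferred), 0L)
})

test_that("termination follows the relative k-mer improvement rule", {
  cfg <- correction_config()  # epsilon = 0.02, max_iter = 5
  expect_equal(check_termination(100000, 99000, 1, cfg), "STOP_EPSILON")
  expect_equal(check_termination(100000, 90000, 1, cfg), "CONTINUE")
  # improvement exactly epsilon continues (strict less-than)
  expect_equal(check_termination(100, 98, 1, cfg), "CONTINUE")
  expect_equal(check_termination(100, 99, 1, cfg), "STOP_EPSILON")
  # negative improvement stops too
  expect_equal(check_termination(100, 120, 1, cfg), "STOP_EPSILON")
  # the iteration cap dominates, whatever the counts
  expect_equal(check_termination(100000, 50000, 5, cfg), "STOP_MAXITER")
  # degenerate zero baseline
  expect_equal(check_termination(0, 0, 1, cfg), "STOP_EPSILON")
})

test_that("the built-in aligner recovers a perfect embedded read", {
  set.seed(61)
  longs <- read_set("L1", random_bases(400))
  shorts <- read_set("q1", substr(longs$seq, 101, 200),
                     phred_encode(rep(35L, 100)))
  aln <- align_short_reads(longs, shorts)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 100L)
  expect_equal(aln$identity, 1.0)
  expect_equal(aln$cigar, "100=")
})

test_that("the built-in aligner handles reverse-strand reads", {
  set.seed(62)
  longs <- read_set("L1", random_bases(400))
  frag <- substr(longs$seq, 151, 250)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag)))
  shorts <- read_set("q1", rc, phred_encode(c(2L, rep(35L, 98), 3L)))
  aln <- align_short_reads(longs, shorts)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$strand, "-")
  expect_equal(aln$start, 150L)
  expect_equal(aln$identity, 1.0)
  # SEQ and QUAL are reported in long-read orientation
  expect_equal(aln$seq, frag)
  expect_equal(phred_decode(aln$qual)[[1]][1], 3L)
})

test_that("correcting an error raises the realigned identity", {
  set.seed(63)
  truth <- random_bases(300)
  noisy <- truth
  substr(noisy, 150, 150) <- if (substr(truth, 150, 150) == "A") "C" else "A"
  longs <- read_set("L1", noisy)
  shorts <- read_set(sprintf("q%d", 1:4),
                     vapply(c(101, 111, 121, 131), function(p)
                       substr(truth, p, p + 99), character(1)),
                     rep(phred_encode(rep(35L, 100)), 4))
  before <- align_short_reads(longs, shorts)
  run <- correct_long_reads(longs, shorts, iterative = FALSE,
                            config = correction_config(min_coverage = 2L))
  expect_equal(run$reads$seq, truth)
  after <- align_short_reads(run$reads, shorts)
  expect_true(mean(after$identity) > mean(before$identity))
})

test_that("long reads with no shared seeds pass through uncorrected", {
  longs <- read_set("L1", strrep("ACGT", 50))
  shorts <- read_set("q1", strrep("T", 60), strrep("I", 60))
  aln <- align_short_reads(longs, shorts)
  expect_equal(nrow(aln), 0L)
  run <- correct_long_reads(longs, shorts, iterative = TRUE)
  expect_equal(run$reads$seq, longs$seq)
  expect_equal(nrow(run$iterations), 1L)
})

test_that("a single pass equals the iterative loop with a vanishing alpha", {
  sim <- small_sim()
  single <- correct_long_reads(sim$long_reads, sim$short_reads,
                               alignments = sim$alignments,
                               iterative = FALSE)
  allhi <- correct_long_reads(sim$long_reads, sim$short_reads,
                              alignments = sim$alignments,
                              config = correction_config(alpha = 1e-6,
                                                         max_iter = 1L),
                              iterative = TRUE)
  expect_identical(single$reads$seq, allhi$reads$seq)
})

test_that("an external aligner command template is substituted and parsed", {
  set.seed(64)
  longs <- read_set("L1", random_bases(120))
  shorts <- read_set("q1", substr(longs$seq, 21, 60),
                     phred_encode(rep(30L, 40)))
  ref_sam <- tempfile(fileext = ".sam")
  write_sam(aln_row("q1", "L1", 20, "40M", substr(longs$seq, 21, 60),
                    phred_encode(rep(30L, 40)), longs$seq),
            longs, ref_sam)
  tpl <- paste("cp", ref_sam, "{out}")
  aln <- realign_reads(longs, shorts, aligner = tpl)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 20L)
  # nonzero exit becomes a hard error
  expect_error(realign_reads(longs, shorts, aligner = "false # {out}"),
               "external aligner failed")
  unlink(ref_sam)
})

test_that("locked sites grow monotonically and never revert", {
  sim <- small_sim()
  run <- correct_long_reads(sim$long_reads, sim$short_reads,
                            alignments = sim$alignments, iterative = TRUE)
  sizes <- vapply(run$lock_history, nrow, integer(1))
  expect_true(all(diff(sizes) >= 0))
  # every base-content lock still matches the final sequence
  lk <- run$locked[!is.na(base)]
  expect_true(nrow(lk) > 0)
  seqs <- stats::setNames(run$reads$seq, run$reads$id)
  expect_true(all(substring(seqs[lk$rname], lk$pos + 1, lk$pos + 1) ==
                  lk$base))
})
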