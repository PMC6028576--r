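test_that("quality weights normalise by the site maximum", {
  expect_equal(normalize_quality_weights(c(30, 40, 20)), c(0.75, 1.0, 0.5))
  expect_equal(normalize_quality_weights(17), 1.0)
  expect_equal(normalize_quality_weights(c(0, 0)), c(0, 0))
  expect_error(normalize_quality_weights(numeric(0)))
})

test_that("the cost is the equal-weight convex combination, bounded and monotone", {
  expect_equal(correction_cost(1, 1), 1)
  expect_equal(correction_cost(0.8, 0.6), 0.7)
  expect_equal(correction_cost(0, 0), 0)
  expect_error(correction_cost(1.2, 0.5))
  set.seed(1)
  w <- matrix(runif(400), ncol = 2)
  J <- correction_cost(w[, 1], w[, 2])
  expect_true(all(J >= 0 & J <= 1))
  # monotone nondecreasing in each argument
  eps <- 0.05
  expect_true(all(correction_cost(pmin(1, w[, 1] + eps), w[, 2]) >= J))
  expect_true(all(correction_cost(w[, 1], pmin(1, w[, 2] + eps)) >= J))
})

test_that("quick correction requires the strong-consensus fraction", {
  # 9 of 10 covering reads propose A over long-base G at eta = 0.9
  s9 <- make_site(q = rep(30L, 10), identity = rep(0.9, 10),
                  agree = c(rep(FALSE, 9), TRUE))
  d <- quick_correct(s9, eta = 0.9)
  expect_equal(d$origin, "QUICK")
  expect_equal(d$type, "SUB")
  expect_equal(d$edit, "A")
  # 8 of 10 is below threshold
  s8 <- make_site(q = rep(30L, 10), identity = rep(0.9, 10),
                  agree = c(rep(FALSE, 8), TRUE, TRUE))
  expect_null(quick_correct(s8, eta = 0.9))
  # coverage gate
  s1 <- make_site(q = 30L, identity = 0.9, agree = FALSE, coverage = 1L)
  expect_null(quick_correct(s1, eta = 0.9, min_coverage = 2L))
})

test_that("optimal selection maximises the cost with the quality tie-break", {
  # (w_q, w_s) = (1.0, 0.9) vs (0.5, 1.0): J = 0.95 vs 0.75
  s <- make_site(q = c(40L, 20L), identity = c(0.9, 1.0),
                 agree = c(FALSE, FALSE), edit = c("A", "C"),
                 qname = c("sA", "sB"))
  d <- select_optimal(s)
  expect_equal(d$winner, "sA")
  expect_equal(d$J, 0.95)
  expect_equal(d$edit, "A")
  # exact tie on J (= 0.75 both): the higher-quality read wins
  s2 <- make_site(q = c(20L, 40L), identity = c(1.0, 0.5),
                  agree = c(FALSE, FALSE), edit = c("A", "C"),
                  qname = c("sA", "sB"))
  d2 <- select_optimal(s2)
  expect_equal(d2$winner, "sB")
  # single disagreeing vote wins with its own J
  s3 <- make_site(q = 25L, identity = 0.7, agree = FALSE)
  d3 <- select_optimal(s3)
  expect_equal(d3$J, (1 + 0.7) / 2)
  expect_equal(d3$origin, "OPTIMIZED")
})

test_that("an agreeing winner keeps the long-read base unchanged", {
  s <- make_site(q = c(rep(40L, 5), 10L),
                 identity = c(rep(0.99, 5), 0.99),
                 agree = c(rep(TRUE, 5), FALSE))
  d <- select_optimal(s)
  expect_true(isTRUE(d$keep))
  # and the bulk path emits no decision for such a site
  sim_votes <- data.table::data.table(
    rname = "L1", pos = 5L, is_ins = 0L, qname = s$votes$short_read_id,
    type = s$votes$type, edit = s$votes$edit, q = s$votes$q,
    identity = s$votes$identity, agree = s$votes$agree, coverage = 6L,
    long_base = "G")
  pl <- structure(list(votes = sim_votes,
                       sites = sim_votes[1, .(rname, pos, is_ins)],
                       coverage = list(L1 = rep(6L, 10))), class = "pileup")
  dec <- decide_sites(pl, correction_config(min_coverage = 1L))
  expect_equal(nrow(dec), 0L)
})

test_that("optimal selection agrees with brute-force enumeration", {
  set.seed(20240915)
  for (i in 1:1200) {
    site <- rand_site()
    got <- select_optimal(site)
    want <- oracle_optimal(site)
    if (want$agree) {
      expect_true(isTRUE(got$keep))
    } else {
      expect_equal(got$winner, want$winner)
      expect_equal(got$J, want$J)
      expect_equal(got$type, want$type)
      expect_equal(got$edit, want$edit)
    }
  }
})

test_that("quick and optimal corrections coincide under perfect consensus", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(2:20, 1)
    type <- sample(c("SUB", "DEL", "INS"), 1)
    edit <- switch(type, SUB = "A", DEL = "", INS = random_bases(2))
    site <- make_site(q = sample(1:41, n, replace = TRUE),
                      identity = round(runif(n), 3),
                      agree = rep(FALSE, n), type = rep(type, n),
                      edit = rep(edit, n), coverage = n)
    dq <- quick_correct(site, eta = 1)
    do <- select_optimal(site)
    expect_equal(dq$type, do$type)
    expect_equal(dq$edit, do$edit)
  }
})

test_that("edits apply correctly and leave other positions untouched", {
  # no decisions: identity
  r0 <- correct_read("ACGTG", NULL)
  expect_equal(r0$seq, "ACGTG")
  expect_equal(r0$pos_map, 0:4)
  # single substitution at position 3
  d1 <- data.table::data.table(pos = 3L, is_ins = 0L, type = "SUB",
                               edit = "A")
  expect_equal(correct_read("ACGTG", d1)$seq, "ACGAG")
  # DELETE at 1 and SUBSTITUTE(T) at 3: oracle = edit an explicit char list
  d2 <- data.table::data.table(pos = c(1L, 3L), is_ins = c(0L, 0L),
                               type = c("DEL", "SUB"), edit = c("", "T"))
  r2 <- correct_read("ACGTG", d2)
  expect_equal(r2$seq, "AGTG")
  expect_equal(r2$pos_map, c(0L, NA_integer_, 1L, 2L, 3L))
  # insertion before position 2
  d3 <- data.table::data.table(pos = 2L, is_ins = 1L, type = "INS",
                               edit = "TT")
  r3 <- correct_read("ACGTG", d3)
  expect_equal(r3$seq, "ACTTGTG")
  expect_equal(r3$pos_map, c(0L, 1L, 4L, 5L, 6L))
})

test_that("length change equals insertions added minus deletions applied", {
  set.seed(12)
  for (i in 1:50) {
    L <- sample(20:60, 1)
    s <- random_bases(L)
    npos <- sample(1:8, 1)
    pos <- sort(sample(0:(L - 1), npos))
    type <- sample(c("SUB", "DEL", "INS"), npos, replace = TRUE)
    is_ins <- as.integer(type == "INS")
    edit <- vapply(type, function(tp) switch(tp, SUB = random_bases(1),
                                             DEL = "",
                                             INS = random_bases(sample(1:3, 1))),
                   character(1))
    dd <- data.table::data.table(pos = pos, is_ins = is_ins, type = type,
                                 edit = edit)
    dd <- dd[!duplicated(dd[, c("pos", "is_ins")])]
    r <- correct_read(s, dd)
    gained <- sum(nchar(dd$edit[dd$type == "INS"]))
    lost <- sum(dd$type == "DEL")
    expect_equal(nchar(r$seq), L + gained - lost)
    # non-site positions are bitwise unchanged (check via the position map)
    untouched <- setdiff(0:(L - 1), dd$pos[dd$is_ins == 0L])
    mapped <- r$pos_map[untouched + 1L]
    expect_equal(substring(r$seq, mapped + 1L, mapped + 1L),
                 substring(s, untouched + 1L, untouched + 1L))
  }
})
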