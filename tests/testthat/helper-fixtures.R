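# Shared fixtures and independent oracles, all built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# small synthetic data set reused across test files (cached per session)
small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_hybrid_data(sim_config(
      reference_length = 8000L, n_long = 6L, long_length = c(1500L, 2500L),
      coverage = 30, seed = 7L))
  }
  .fixture_env$small
}

# full-scale study-condition fixture used by the end-to-end tests
ci_sim <- function() {
  if (is.null(.fixture_env$ci)) {
    .fixture_env$ci <- simulate_hybrid_data(sim_config(seed = 7L))
  }
  .fixture_env$ci
}

random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

# construct a site-evidence list directly (bypassing the pileup)
make_site <- function(q, identity, agree, type = NULL, edit = NULL,
                      coverage = NULL, qname = NULL, long_base = "G",
                      position = 5L, is_insert = FALSE) {
  n <- length(q)
  if (is.null(qname)) qname <- sprintf("s%02d", seq_len(n))
  if (is.null(type)) type <- rep("SUB", n)
  if (is.null(edit)) edit <- ifelse(agree, long_base, "A")
  if (is.null(coverage)) coverage <- n
  list(long_read_id = "L1", position = position, is_insert = is_insert,
       long_base = long_base, coverage = coverage,
       votes = data.frame(short_read_id = qname, type = type, edit = edit,
                          q = as.integer(q), identity = identity,
                          agree = agree, stringsAsFactors = FALSE))
}

# a random questionable site with 2-30 votes, mixed edit kinds and agreement
rand_site <- function() {
  n <- sample(2:30, 1)
  agree <- runif(n) < 0.4
  type <- ifelse(agree, "SUB",
                 sample(c("SUB", "DEL", "INS"), n, replace = TRUE))
  long_base <- sample(c("A", "C", "G", "T"), 1)
  edit <- character(n)
  for (i in seq_len(n)) {
    edit[i] <- if (agree[i]) long_base
    else switch(type[i],
                SUB = sample(setdiff(c("A", "C", "G", "T"), long_base), 1),
                DEL = "",
                INS = random_bases(sample(1:3, 1)))
  }
  make_site(q = sample(0:41, n, replace = TRUE),
            identity = round(runif(n), 3), agree = agree, type = type,
            edit = edit, long_base = long_base,
            coverage = n + sample(0:5, 1))
}

# brute-force enumeration oracle for the optimization step: evaluates the
# cost of every aligned read and applies the tie-break chain explicitly
oracle_optimal <- function(site) {
  v <- site$votes
  m <- max(v$q)
  wq <- if (m == 0) rep(0, nrow(v)) else v$q / m
  J <- (wq + v$identity) / 2
  best <- 1L
  for (i in seq_len(nrow(v))[-1]) {
    if (J[i] > J[best]) best <- i
    else if (J[i] == J[best]) {
      if (v$q[i] > v$q[best]) best <- i
      else if (v$q[i] == v$q[best] &&
               v$short_read_id[i] < v$short_read_id[best]) best <- i
    }
  }
  list(winner = v$short_read_id[best], J = J[best], agree = v$agree[best],
       type = v$type[best], edit = v$edit[best])
}

# naive k-mer enumeration oracle (loops, no set tricks shared with the
# implementation beyond base R unique/intersect)
oracle_kmer_set <- function(seqs, k, canonical = FALSE) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("N", km, fixed = TRUE)) next
      if (canonical) {
        rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", km), "")[[1]]),
                    collapse = "")
        km <- min(km, rc)
      }
      out <- c(out, km)
    }
  }
  unique(out)
}

# build an alignment table row with identity computed independently
aln_row <- function(qname, rname, start, cigar, seq, qual, long_seq) {
  data.table::data.table(
    qname = qname, rname = rname, start = as.integer(start),
    strand = "+", cigar = cigar, seq = seq, qual = qual,
    identity = alignment_identity(start, cigar, seq, long_seq))
}

random_read_set <- function(n, with_qual = TRUE, maxlen = 120L) {
  lens <- sample(10:maxlen, n, replace = TRUE)
  seqs <- vapply(lens, random_bases, character(1))
  qual <- if (with_qual)
    vapply(lens, function(L) phred_encode(sample(0:93, L, replace = TRUE)),
           character(1))
  else NULL
  read_set(sprintf("r%04d", seq_len(n)), seqs, qual)
}
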