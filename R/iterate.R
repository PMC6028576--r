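#' Per-iteration confidence threshold over optimal costs
#'
#' The nearest-rank alpha-percentile of the iteration's optimal costs: the
#' value at rank `ceiling(alpha/100 * N)` of the ascending-sorted list.
#' Corrections with optimal cost at or above this threshold are deemed high
#' confidence.
#'
#' @param costs numeric vector of optimal costs (one per optimization-based
#'   decision).
#' @param alpha percentile in (0, 100).
#' @return The threshold value.
#' @examples
#' confidence_threshold(seq(0.01, 1, by = 0.01), 95)  # 0.95
#' @export
confidence_threshold <- function(costs, alpha = 95) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 100)
  costs <- costs[!is.na(costs)]
  if (!length(costs)) stop("need at least one cost")
  s <- sort(costs)
  s[max(1L, ceiling(alpha / 100 * length(s)))]
}

#' Split decisions into applied and deferred sets
#'
#' Quick (strong-consensus) corrections are always applied; optimization-
#' based corrections are applied only when their optimal cost reaches the
#' high-confidence threshold `mu`. Deferred sites stay eligible in later
#' iterations, where realignment may present fresh evidence for them.
#'
#' @param decisions decisions `data.table` from [decide_sites()].
#' @param mu high-confidence threshold (from [confidence_threshold()]); `NA`
#'   when the iteration produced no optimization-based decision.
#' @return A list with `applied` and `deferred` decision tables.
#' @export
apply_high_confidence <- function(decisions, mu) {
  decisions <- as.data.table(decisions)
  hi <- decisions$origin == "QUICK" |
    (!is.na(decisions$J) & !is.na(mu) & decisions$J >= mu)
  list(applied = decisions[hi], deferred = decisions[!hi])
}

#' Termination test for the iterative loop
#'
#' Stops with `STOP_MAXITER` once the iteration cap is reached; otherwise
#' stops with `STOP_EPSILON` when the relative improvement in unique k-mers,
#' `(prev - curr) / prev`, falls below `epsilon` (strictly; an improvement of
#' exactly `epsilon` continues). A non-positive previous count degenerately
#' stops.
#'
#' @param unique_kmers_prev unique k-mer count after the previous iteration
#'   (iteration 0 = the uncorrected input).
#' @param unique_kmers_curr unique k-mer count after the current iteration.
#' @param iteration current iteration index (>= 1).
#' @param config a [correction_config()] (uses `epsilon` and `max_iter`).
#' @return One of `"CONTINUE"`, `"STOP_EPSILON"`, `"STOP_MAXITER"`.
#' @export
check_termination <- function(unique_kmers_prev, unique_kmers_curr,
                              iteration, config = correction_config()) {
  stopifnot(iteration >= 1L)
  if (iteration >= config$max_iter) return("STOP_MAXITER")
  if (unique_kmers_prev <= 0) return("STOP_EPSILON")
  rel <- (unique_kmers_prev - unique_kmers_curr) / unique_kmers_prev
  if (rel < config$epsilon) "STOP_EPSILON" else "CONTINUE"
}

#' Built-in seed-and-extend aligner configuration
#'
#' A light short-to-long read aligner used for realignment when no external
#' aligner is configured: exact k-mer seeds (default 13) vote for a (long
#' read, strand, diagonal) candidate per short read, and the short read is
#' then aligned end-to-end against the seeded long-read window with a banded
#' dynamic program (default band 32). Alignments below `min_identity` are
#' discarded. Intended for package-scale data; an external aligner command
#' is preferred at genome scale.
#'
#' @param seed_k seed k-mer length.
#' @param band half-width of the alignment band.
#' @param min_identity minimum alignment identity to keep an alignment.
#' @param seed_stride distance between successive seed start positions on
#'   the short read.
#' @param max_kmer_hits seeds occurring more often than this in the long
#'   reads are considered repetitive and ignored.
#' @return An aligner configuration object.
#' @export
builtin_aligner <- function(seed_k = 13L, band = 32L, min_identity = 0.6,
                            seed_stride = 6L, max_kmer_hits = 20L) {
  structure(list(seed_k = as.integer(seed_k), band = as.integer(band),
                 min_identity = min_identity,
                 seed_stride = as.integer(seed_stride),
                 max_kmer_hits = as.integer(max_kmer_hits)),
            class = "builtin_aligner")
}

#' Align short reads to long reads with the built-in aligner
#'
#' @param long_reads,short_reads [read_set]s.
#' @param aligner a [builtin_aligner()] configuration.
#' @return An alignment `data.table` in the same shape as [read_sam()].
#' @export
align_short_reads <- function(long_reads, short_reads,
                              aligner = builtin_aligner()) {
  stopifnot(inherits(aligner, "builtin_aligner"))
  k <- aligner$seed_k
  band <- aligner$band
  # k-mer index over the long reads
  idx <- rbindlist(lapply(seq_along(long_reads$id), function(i) {
    s <- long_reads$seq[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
               rname = long_reads$id[i], lpos = 0:(n - k))
  }))
  if (is.null(idx) || !nrow(idx)) return(empty_alignments())
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  idx[, hits := .N, by = kmer]
  idx <- idx[hits <= aligner$max_kmer_hits][, hits := NULL]
  setkey(idx, kmer)

  fwd <- short_reads$seq
  rcs <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
  seeds <- rbindlist(lapply(c("+", "-"), function(st) {
    sq <- if (st == "+") fwd else rcs
    rbindlist(lapply(seq_along(sq), function(i) {
      n <- nchar(sq[i])
      if (n < k) return(NULL)
      sp <- seq.int(1L, n - k + 1L, by = aligner$seed_stride)
      data.table(qid = i, strand = st, spos = sp - 1L,
                 kmer = substring(sq[i], sp, sp + k - 1L))
    }))
  }))
  if (!nrow(seeds)) return(empty_alignments())
  m <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(m)) return(empty_alignments())
  m[, diag0 := lpos - spos]
  m[, dbin := diag0 %/% 16L]
  cand <- m[, .(hits = .N, diag0 = as.integer(median(diag0))),
            by = .(qid, strand, rname, dbin)]
  setorder(cand, qid, -hits, strand, rname, dbin)
  best <- cand[, head(.SD, 1L), by = qid]
  if (!nrow(best)) return(empty_alignments())

  lseq <- setNames(long_reads$seq, long_reads$id)
  llen <- nchar(lseq)
  slen <- nchar(short_reads$seq)[best$qid]
  wstart <- pmax(0L, best$diag0 - band)
  wend <- pmin(llen[best$rname], best$diag0 + slen + band)
  keep <- wend - wstart >= pmin(slen, 20L)
  best <- best[keep]
  if (!nrow(best)) return(empty_alignments())
  wstart <- wstart[keep]; wend <- wend[keep]; slen <- slen[keep]
  sseq <- ifelse(best$strand == "+", fwd[best$qid], rcs[best$qid])
  wseq <- substring(lseq[best$rname], wstart + 1L, wend)
  aln <- banded_glocal_cpp(sseq, wseq, band)
  ok <- !is.na(aln$start) & aln$matches / slen >= aligner$min_identity
  if (!any(ok)) return(empty_alignments())
  qual <- short_reads$qual
  out_qual <- if (is.null(qual)) rep(NA_character_, sum(ok)) else {
    # qualities in long-read orientation: reversed for '-' strand
    qq <- qual[best$qid[ok]]
    neg <- best$strand[ok] == "-"
    qq[neg] <- vapply(qq[neg], function(s)
      intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
    qq
  }
  data.table(qname = short_reads$id[best$qid[ok]],
             rname = best$rname[ok],
             start = as.integer(wstart[ok] + aln$start[ok]),
             strand = best$strand[ok],
             cigar = aln$cigar[ok],
             seq = sseq[ok],
             qual = out_qual,
             identity = aln$matches[ok] / slen[ok])
}

#' Realign short reads against (corrected) long reads
#'
#' Produces fresh alignments for the next iteration, discarding all prior
#' ones. The aligner is pluggable: either the [builtin_aligner()] or an
#' external command template containing the placeholders `{long}`,
#' `{short}` and `{out}` (e.g. a bwa-mem pipeline writing SAM to `{out}`).
#'
#' @param long_reads,short_reads [read_set]s.
#' @param aligner a [builtin_aligner()] configuration or a character command
#'   template.
#' @return An alignment `data.table`.
#' @export
realign_reads <- function(long_reads, short_reads,
                          aligner = builtin_aligner()) {
  if (inherits(aligner, "builtin_aligner"))
    return(align_short_reads(long_reads, short_reads, aligner))
  if (!is.character(aligner) || length(aligner) != 1L)
    stop("aligner must be a builtin_aligner() or a command template string")
  longf <- tempfile(fileext = ".fasta")
  shortf <- tempfile(fileext = ".fastq")
  outf <- tempfile(fileext = ".sam")
  on.exit(unlink(c(longf, shortf, outf)), add = TRUE)
  write_fasta(long_reads, longf)
  write_fastq(short_reads, shortf)
  cmd <- gsub("{long}", longf, aligner, fixed = TRUE)
  cmd <- gsub("{short}", shortf, cmd, fixed = TRUE)
  cmd <- gsub("{out}", outf, cmd, fixed = TRUE)
  err <- tempfile()
  status <- system(paste0(cmd, " 2> ", shQuote(err)))
  if (status != 0L) {
    errmsg <- if (file.exists(err))
      paste(readLines(err, warn = FALSE), collapse = "\n") else ""
    stop("external aligner failed (exit ", status, "): ", errmsg)
  }
  read_sam(outf, long_reads)
}

#' Correct long reads with short-read evidence
#'
#' The package's main driver. One pass builds the pileup of short-read
#' evidence over every long read, quick-corrects strong-consensus sites and
#' solves the cost-maximisation at the rest, then applies the chosen edits.
#' With `iterative = TRUE`, only quick corrections and optimization-based
#' corrections whose optimal cost reaches the per-iteration alpha-percentile
#' threshold are applied; applied sites are locked (never re-decided, never
#' reverted), the short reads are realigned against the updated long reads,
#' and the loop repeats until the relative unique-k-mer improvement drops
#' below `epsilon` or `max_iter` is reached. With `iterative = FALSE` every
#' decision of the single pass is applied.
#'
#' @param long_reads a [read_set] of noisy long reads.
#' @param short_reads a [read_set] of accurate short reads with qualities.
#' @param alignments optional initial alignments (from [read_sam()] or an
#'   aligner); computed with `aligner` when omitted.
#' @param config a [correction_config()].
#' @param iterative logical; run the iterative learning loop (default) or a
#'   single pass applying all decisions.
#' @param aligner aligner used for (re)alignment: [builtin_aligner()] or an
#'   external command template (see [realign_reads()]).
#' @param verbose print per-iteration progress.
#' @return An object of class `hybridec_run`: a list with `reads` (corrected
#'   long reads), `iterations` (per-iteration report data.frame: `iteration`,
#'   `mu`, `n_quick`, `n_optimized_applied`, `n_deferred`, `unique_kmers`,
#'   `verdict`), `locked` (final locked coordinates), `pos_maps` (per-read
#'   map from input to output coordinates), `config`, and `iterative`.
#' @export
correct_long_reads <- function(long_reads, short_reads, alignments = NULL,
                               config = correction_config(),
                               iterative = TRUE,
                               aligner = builtin_aligner(),
                               verbose = FALSE) {
  stopifnot(inherits(long_reads, "read_set"),
            inherits(short_reads, "read_set"),
            inherits(config, "hybridec_config"))
  reads <- long_reads
  locked <- data.table(rname = character(0), pos = integer(0),
                       is_ins = integer(0))
  total_maps <- lapply(setNames(nchar(reads$seq), reads$id),
                       function(n) seq_len(n) - 1L)
  uk_prev <- unique_kmers(reads, config$k)
  iters <- list()
  lock_history <- list()
  max_l <- if (iterative) config$max_iter else 1L
  for (l in seq_len(max_l)) {
    if (is.null(alignments))
      alignments <- realign_reads(reads, short_reads, aligner)
    pl <- build_pileup(alignments, reads)
    dec <- decide_sites(pl, config, locked)
    if (iterative) {
      opt_costs <- dec$J[dec$origin == "OPTIMIZED"]
      mu <- if (length(opt_costs)) confidence_threshold(opt_costs,
                                                        config$alpha)
      else NA_real_
      sp <- apply_high_confidence(dec, mu)
      applied <- sp$applied
      deferred <- sp$deferred
    } else {
      mu <- NA_real_
      applied <- dec
      deferred <- empty_decisions()
    }
    snapshot <- list(reads = reads, maps = total_maps, locked = locked)
    ap <- apply_decisions(reads, applied, locked)
    reads <- ap$reads
    locked <- ap$locked
    total_maps <- Map(function(tm, pm) {
      out <- rep(NA_integer_, length(tm))
      ok <- !is.na(tm)
      out[ok] <- pm[tm[ok] + 1L]
      out
    }, total_maps, ap$pos_maps[names(total_maps)])
    uk <- unique_kmers(reads, config$k)
    verdict <- if (!iterative) "SINGLE_PASS"
    else check_termination(uk_prev, uk, l, config)
    rolled_back <- FALSE
    if (iterative && uk > uk_prev) {
      warning("unique k-mers increased in iteration ", l,
              "; emitting the previous iteration's reads")
      reads <- snapshot$reads
      total_maps <- snapshot$maps
      locked <- snapshot$locked
      verdict <- "STOP_EPSILON"
      rolled_back <- TRUE
      uk <- uk_prev
    }
    iters[[l]] <- data.frame(
      iteration = l, mu = mu,
      n_quick = sum(applied$origin == "QUICK"),
      n_optimized_applied = sum(applied$origin == "OPTIMIZED"),
      n_deferred = nrow(deferred),
      unique_kmers = uk, verdict = verdict,
      stringsAsFactors = FALSE)
    lock_history[[l]] <- copy(locked)
    if (verbose)
      message(sprintf(
        "iteration %d: mu=%s quick=%d optimized=%d deferred=%d uk=%d %s",
        l, format(mu, digits = 4), iters[[l]]$n_quick,
        iters[[l]]$n_optimized_applied, iters[[l]]$n_deferred, uk, verdict))
    if (rolled_back || verdict != "CONTINUE") break
    uk_prev <- uk
    alignments <- NULL  # force realignment against the updated reads
  }
  structure(list(reads = reads,
                 iterations = do.call(rbind, iters),
                 locked = locked,
                 lock_history = lock_history,
                 pos_maps = total_maps,
                 config = config,
                 iterative = iterative),
            class = "hybridec_run")
}

#' @export
print.hybridec_run <- function(x, ...) {
  it <- x$iterations
  cat("hybridec_run:", length(x$reads), "long read(s),",
      nrow(it), "iteration(s),",
      "final verdict:", it$verdict[nrow(it)], "\n")
  invisible(x)
}

#' @export
summary.hybridec_run <- function(object, ...) {
  cat("Hybrid error correction run",
      if (object$iterative) "(iterative)" else "(single pass)", "\n")
  print(object$config)
  print(object$iterations, row.names = FALSE)
  invisible(object$iterations)
}

#' Write the per-iteration report as tab-separated text
#'
#' @param run a [correct_long_reads()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_iteration_report <- function(run, path) {
  stopifnot(inherits(run, "hybridec_run"))
  write.table(run$iterations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
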